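# Group-level statistics: paired t with Bonferroni correction, mixed-design
# ANOVA with Greenhouse-Geisser correction, Pearson correlation.

#' Paired t-test with Bonferroni correction
#'
#' Two-sided paired t-test; the adjusted p-value is `min(1, m * p_raw)` for a
#' family of `m` comparisons.
#'
#' @param values_a,values_b Paired numeric vectors (same subjects, length
#'   >= 3).
#' @param m_comparisons Family size for the Bonferroni correction.
#' @return One-row tibble: `t`, `df`, `p_raw`, `p_adjusted`, `mean_diff`.
#' @export
paired_t_bonferroni <- function(values_a, values_b, m_comparisons = 1) {
  if (length(values_a) != length(values_b)) {
    abort("Paired vectors must have equal length.")
  }
  if (length(values_a) < 3) abort("Need >= 3 pairs.")
  m <- assert_count(m_comparisons, "m_comparisons")
  d <- values_a - values_b
  if (sd(d) == 0) {
    # degenerate identical vectors: t = 0 by convention
    return(tibble(t = 0, df = length(d) - 1, p_raw = 1, p_adjusted = 1,
                  mean_diff = mean(d)))
  }
  tt <- t.test(values_a, values_b, paired = TRUE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p_raw = tt$p.value,
         p_adjusted = min(1, m * tt$p.value),
         mean_diff = unname(tt$estimate))
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return One-row tibble: `r`, `df`, `t`, `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Need >= 3 observations.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero variance in `x` or `y`.")
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), df = unname(ct$parameter),
         t = unname(ct$statistic), p = ct$p.value)
}

#' Mixed-design ANOVA with Greenhouse-Geisser correction
#'
#' One between-subjects factor crossed with one within-subjects factor,
#' fitted as a multivariate linear model and evaluated with type-III
#' univariate repeated-measures tests (sum-to-zero contrasts). Within-subject
#' and interaction effects additionally get Greenhouse-Geisser-corrected
#' degrees of freedom and p-values; with two within levels sphericity holds
#' trivially and epsilon is exactly 1.
#'
#' @param data Tibble in long format.
#' @param dv,subject,between,within Column names (strings) of the dependent
#'   variable, subject identifier, between factor and within factor.
#' @return An object of class `mixed_anova`; see [tidy.mixed_anova()].
#' @export
mixed_anova_gg <- function(data, dv, subject, between, within) {
  df <- as_tibble(data)
  for (col in c(dv, subject, between, within)) {
    if (!col %in% names(df)) abort(sprintf("Column `%s` not found.", col))
  }
  wide <- df |>
    select(all_of(c(subject, between, within, dv))) |>
    tidyr::pivot_wider(names_from = all_of(within),
                       values_from = all_of(dv))
  lvls <- unique(as.character(df[[within]]))
  k <- length(lvls)
  grp <- factor(wide[[between]])
  if (nlevels(grp) < 2) abort("Need >= 2 between-subject groups.")
  if (k < 2) abort("Need >= 2 within-subject levels.")
  if (min(table(grp)) < 2) abort("Need >= 2 subjects per group.")
  Y <- as.matrix(wide[, lvls])
  if (anyNA(Y)) abort("Design is not fully crossed (missing cells).")
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  mlm <- lm(Y ~ grp)
  idata <- data.frame(level = factor(lvls, levels = lvls))
  an <- car::Anova(mlm, idata = idata, idesign = ~level, type = 3)
  # car warns when the Huynh-Feldt epsilon exceeds 1; only GG is used here
  s <- suppressWarnings(summary(an, multivariate = FALSE))
  ut <- s$univariate.tests
  res <- tibble(
    effect = c("between", "within", "interaction"),
    term = c(between, within, paste0(between, ":", within)),
    sum_sq = unname(ut[c("grp", "level", "grp:level"), "Sum Sq"]),
    df1 = unname(ut[c("grp", "level", "grp:level"), "num Df"]),
    error_ss = unname(ut[c("grp", "level", "grp:level"), "Error SS"]),
    df2 = unname(ut[c("grp", "level", "grp:level"), "den Df"]),
    F = unname(ut[c("grp", "level", "grp:level"), "F value"]),
    p = unname(ut[c("grp", "level", "grp:level"), "Pr(>F)"]))
  if (k == 2) {
    eps <- 1
  } else {
    pv <- s$pval.adjustments
    eps <- unname(pv["level", "GG eps"])
  }
  res$gg_epsilon <- c(NA_real_, eps, eps)
  res$df1_gg <- ifelse(is.na(res$gg_epsilon), res$df1,
                       res$df1 * res$gg_epsilon)
  res$df2_gg <- ifelse(is.na(res$gg_epsilon), res$df2,
                       res$df2 * res$gg_epsilon)
  res$p_gg <- ifelse(is.na(res$gg_epsilon), res$p,
                     pf(res$F, res$df1_gg, res$df2_gg, lower.tail = FALSE))
  structure(list(table = res, k_within = k, n_subjects = nrow(wide),
                 levels = lvls, between = between, within = within),
            class = "mixed_anova")
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat(sprintf("Mixed ANOVA: %s (between) x %s (%d levels, within), n = %d\n",
              x$between, x$within, x$k_within, x$n_subjects))
  tb <- x$table
  for (i in seq_len(nrow(tb))) {
    cat(sprintf("  %-12s F(%.4g, %.4g) = %.3f, p = %.4f%s\n",
                tb$effect[i], tb$df1_gg[i], tb$df2_gg[i], tb$F[i],
                tb$p_gg[i],
                if (!is.na(tb$gg_epsilon[i]))
                  sprintf(" (GG eps = %.3f)", tb$gg_epsilon[i]) else ""))
  }
  invisible(x)
}

#' Tidy a mixed ANOVA fit
#'
#' @param x A `mixed_anova` object.
#' @param ... Unused.
#' @return A tibble with one row per effect (between, within, interaction):
#'   sums of squares, uncorrected and Greenhouse-Geisser-corrected degrees of
#'   freedom, F and p-values.
#' @export
tidy.mixed_anova <- function(x, ...) x$table

#' @rdname tidy.mixed_anova
#' @return `glance()`: a one-row tibble with the design dimensions and the
#'   interaction test.
#' @export
glance.mixed_anova <- function(x, ...) {
  inter <- x$table[x$table$effect == "interaction", ]
  tibble(n_subjects = x$n_subjects, k_within = x$k_within,
         gg_epsilon = inter$gg_epsilon,
         F_interaction = inter$F, p_interaction_gg = inter$p_gg)
}
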