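# Cohort-level report assembly: the full battery of group comparisons run on
# a cohort table (subject metadata joined to SS-EP and ERP results).

#' Group-level statistical report for a cohort table
#'
#' Reproduces the standard frequency-tagging testing structure on a cohort
#' table: per-frequency paired t-tests of tagged amplitude against the noise
#' floor (Bonferroni-corrected over the tagged family), the beat/meter-
#' related vs unrelated contrast, a group x frequency mixed ANOVA with
#' Greenhouse-Geisser correction plus Bonferroni-corrected per-frequency
#' group contrasts, a group x hemisphere ANOVA on ERP areas, Pearson
#' correlations of ERP magnitude and SS-EP amplitudes with the music-
#' background measures, and the z-score exclusion log. Outlying subjects
#' (|z| > `z_cutoff` on the mean tagged amplitude) are flagged and excluded
#' from the statistics but never dropped from the table.
#'
#' @param cohort_table Tibble, one row per subject: metadata columns
#'   (`subject_id`, `group`, `music_classes`, `parent_trained`,
#'   `parent_training_years`, `listening_hours`), `ssep_<freq>` columns,
#'   `noise_floor`, and optionally `auc_left` / `auc_right`.
#' @param related_hz Beat- and meter-related frequencies.
#' @param anova_freqs Frequencies (within-subject levels) entering the
#'   group x frequency ANOVA; default: all `ssep_` columns.
#' @param between One of `"music_classes"` or `"parent_trained"`: the
#'   between-subjects grouping.
#' @param alpha Significance level for flags.
#' @param posthoc_alpha Family-wise alpha for the per-frequency post-hoc
#'   family.
#' @param z_cutoff Outlier exclusion cutoff.
#' @param out_dir Optional directory; when given, every table is written as
#'   CSV plus a plain-text summary (`report.txt`).
#' @return List of tibbles: `inclusion`, `tagged_vs_noise`,
#'   `related_vs_unrelated`, `anova_group_by_freq`, `posthoc_by_freq`,
#'   `erp_anova`, `correlations`.
#' @export
build_report <- function(cohort_table, related_hz = c(1, 1.5, 3),
                         anova_freqs = NULL,
                         between = c("music_classes", "parent_trained"),
                         alpha = 0.05, posthoc_alpha = 0.10, z_cutoff = 3,
                         out_dir = NULL) {
  between <- match.arg(between)
  tb <- as_tibble(cohort_table)
  amp_cols <- ssep_columns(tb)
  if (length(amp_cols) == 0) abort("No `ssep_` amplitude columns found.")
  needed <- c("subject_id", between, "noise_floor")
  missing <- setdiff(needed, names(tb))
  if (length(missing) > 0) {
    abort(paste0("Missing column(s): ", paste(missing, collapse = ", ")))
  }
  freqs <- as.numeric(sub("^ssep_", "", amp_cols))

  # outlier screening on the mean tagged amplitude
  score <- rowMeans(tb[, amp_cols])
  included <- zscore_exclude(score, z_cutoff)
  inclusion <- tibble(subject_id = tb$subject_id, mean_tagged_uv = score,
                      z = if (sd(score) == 0) 0 else
                        (score - mean(score)) / sd(score),
                      included = included)
  use <- tb[included, ]

  col_for <- function(f) amp_cols[which.min(abs(freqs - f))]

  tagged_vs_noise <- purrr::map_dfr(seq_along(amp_cols), function(i) {
    res <- paired_t_bonferroni(use[[amp_cols[i]]], use$noise_floor,
                               m_comparisons = length(amp_cols))
    mutate(res, frequency_hz = freqs[i],
           significant = .data$p_adjusted < alpha, .before = 1)
  })

  unrelated_hz <- setdiff(freqs, related_hz)
  related_vs_unrelated <- if (length(unrelated_hz) > 0) {
    rel <- rowMeans(use[, vapply(intersect(related_hz, freqs), col_for,
                                 character(1)), drop = FALSE])
    unrel <- rowMeans(use[, vapply(unrelated_hz, col_for, character(1)),
                          drop = FALSE])
    mutate(paired_t_bonferroni(rel, unrel),
           significant = .data$p_adjusted < alpha)
  } else {
    tibble()
  }

  anova_freqs <- anova_freqs %||% freqs
  long <- use |>
    select(all_of(c("subject_id", between,
                    vapply(anova_freqs, col_for, character(1))))) |>
    tidyr::pivot_longer(cols = all_of(vapply(anova_freqs, col_for,
                                             character(1))),
                        names_to = "frequency", values_to = "amplitude")
  fit <- mixed_anova_gg(long, dv = "amplitude", subject = "subject_id",
                        between = between, within = "frequency")
  anova_tbl <- tidy(fit)
  interaction_sig <-
    anova_tbl$p_gg[anova_tbl$effect == "interaction"] < alpha

  grp_flag <- use[[between]]
  posthoc <- purrr::map_dfr(anova_freqs, function(f) {
    cl <- col_for(f)
    a <- use[[cl]][grp_flag]
    b <- use[[cl]][!grp_flag]
    tt <- t.test(a, b, var.equal = TRUE)
    p_adj <- min(1, length(anova_freqs) * tt$p.value)
    tibble(frequency_hz = f, t = unname(tt$statistic),
           df = unname(tt$parameter), p_raw = tt$p.value,
           p_adjusted = p_adj, mean_group = mean(a), mean_other = mean(b),
           significant = p_adj < posthoc_alpha)
  })

  erp_anova <- NULL
  if (all(c("auc_left", "auc_right") %in% names(tb))) {
    erp_long <- use |>
      select(all_of(c("subject_id", between, "auc_left", "auc_right"))) |>
      tidyr::pivot_longer(c("auc_left", "auc_right"),
                          names_to = "hemisphere", values_to = "auc")
    erp_fit <- mixed_anova_gg(erp_long, dv = "auc", subject = "subject_id",
                              between = between, within = "hemisphere")
    erp_anova <- tidy(erp_fit)
  }

  correlations <- list()
  if (all(c("auc_left", "auc_right") %in% names(tb)) &&
      "parent_training_years" %in% names(tb)) {
    erp_mag <- rowMeans(use[, c("auc_left", "auc_right")])
    correlations$erp_vs_parent_training <-
      mutate(pearson_r(erp_mag, use$parent_training_years),
             x = "erp_auc_mean", y = "parent_training_years", .before = 1)
  }
  if ("listening_hours" %in% names(tb)) {
    correlations <- c(correlations, purrr::map(related_hz, function(f) {
      mutate(pearson_r(use[[col_for(f)]], use$listening_hours),
             x = col_for(f), y = "listening_hours", .before = 1)
    }))
  }
  correlations <- bind_rows(correlations)

  report <- list(inclusion = inclusion,
                 tagged_vs_noise = tagged_vs_noise,
                 related_vs_unrelated = related_vs_unrelated,
                 anova_group_by_freq = anova_tbl,
                 posthoc_by_freq = posthoc,
                 erp_anova = erp_anova,
                 correlations = correlations)
  report$flags <- tibble(
    interaction_significant = interaction_sig,
    duple_contrast_significant =
      any(posthoc$significant[abs(posthoc$frequency_hz - 1.5) < 1e-9]))

  if (!is.null(out_dir)) write_report(report, out_dir, alpha)
  report
}

write_report <- function(report, out_dir, alpha) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report)) {
    if (is.data.frame(report[[nm]]) && nrow(report[[nm]]) > 0) {
      readr::write_csv(report[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
  }
  excl <- report$inclusion[!report$inclusion$included, ]
  lines <- c(
    "Frequency-tagging group report",
    sprintf("alpha = %.3g", alpha),
    "",
    sprintf("Excluded subjects (|z| > cutoff): %s",
            if (nrow(excl) == 0) "none" else
              paste(sprintf("%s (z = %.3f)", excl$subject_id, excl$z),
                    collapse = ", ")),
    "",
    sprintf("Group x frequency interaction: F = %.3f, p(GG) = %.3f",
            report$anova_group_by_freq$F[3],
            report$anova_group_by_freq$p_gg[3]))
  writeLines(lines, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}
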