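# Independent from-scratch oracles used to cross-check the implementation.
# These deliberately share no code path with the package internals.

# Paired t statistic from the textbook formula.
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

# Pearson correlation from the covariance formula with t-based p.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = t, p = 2 * pt(-abs(t), n - 2))
}

# Mixed-design (one between x one within) ANOVA by direct sums-of-squares
# computation: type-3 quadratic forms via explicit projections on a
# sum-coded design matrix, orthonormal within-subject contrasts, and the
# Greenhouse-Geisser epsilon from the error cross-product matrix.
oracle_mixed_anova <- function(Y, grp) {
  grp <- factor(grp)
  n <- nrow(Y); k <- ncol(Y); g <- nlevels(grp)
  # orthonormal contrasts spanning the within-level differences
  C <- qr.Q(qr(cbind(1, diag(k))))[, 2:k, drop = FALSE]

  # sum-coded between design
  Xg <- matrix(0, n, g - 1)
  for (j in seq_len(g - 1)) {
    Xg[grp == levels(grp)[j], j] <- 1
    Xg[grp == levels(grp)[g], j] <- -1
  }
  X <- cbind(1, Xg)
  XtXi <- solve(crossprod(X))
  type3_ss <- function(z, which_cols) {
    beta <- XtXi %*% crossprod(X, z)
    L <- diag(ncol(X))[which_cols, , drop = FALSE]
    lb <- L %*% beta
    drop(t(lb) %*% solve(L %*% XtXi %*% t(L)) %*% lb)
  }
  resid_ss <- function(z) {
    sum((z - X %*% (XtXi %*% crossprod(X, z)))^2)
  }

  # between-subjects part, on subject means scaled by k
  s <- rowMeans(Y)
  ss_between <- k * type3_ss(s, 2:ncol(X))
  ss_subj <- k * resid_ss(s)
  df_between <- g - 1; df_subj <- n - g
  F_between <- (ss_between / df_between) / (ss_subj / df_subj)

  # within-subjects part, on contrast scores
  Z <- Y %*% C
  ss_within <- sum(apply(Z, 2, type3_ss, which_cols = 1))
  ss_inter <- sum(apply(Z, 2, type3_ss, which_cols = 2:ncol(X)))
  ss_err <- sum(apply(Z, 2, resid_ss))
  df_within <- k - 1
  df_inter <- (g - 1) * (k - 1)
  df_err <- (n - g) * (k - 1)
  F_within <- (ss_within / df_within) / (ss_err / df_err)
  F_inter <- (ss_inter / df_inter) / (ss_err / df_err)

  # GG epsilon from the error SSP matrix in contrast space
  R <- Y - apply(Y, 2, function(col) ave(col, grp))
  E <- t(C) %*% crossprod(R) %*% C
  eps <- sum(diag(E))^2 / ((k - 1) * sum(E * t(E)))

  list(F_between = F_between, F_within = F_within,
       F_interaction = F_inter, gg_epsilon = eps,
       p_between = pf(F_between, df_between, df_subj, lower.tail = FALSE),
       p_within = pf(F_within, df_within, df_err, lower.tail = FALSE),
       p_interaction = pf(F_inter, df_inter, df_err, lower.tail = FALSE))
}

# Envelope oracle: build the analytic signal from a known quadrature pair
# m(t) cos(wt) + i m(t) sin(wt), whose modulus is |m(t)| by construction.
oracle_quadrature_envelope <- function(m, carrier_hz, rate_hz) {
  t <- (seq_along(m) - 1) / rate_hz
  Mod(complex(real = m * cos(2 * pi * carrier_hz * t),
              imaginary = m * sin(2 * pi * carrier_hz * t)))
}

# Long-format helper for mixed_anova_gg from a wide amplitude matrix.
long_from_matrix <- function(Y, grp) {
  colnames(Y) <- paste0("w", seq_len(ncol(Y)))
  df <- tibble::as_tibble(Y)
  df$subject_id <- sprintf("S%03d", seq_len(nrow(Y)))
  df$grp <- grp
  tidyr::pivot_longer(df, dplyr::starts_with("w"),
                      names_to = "level", values_to = "value")
}
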