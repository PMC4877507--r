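# Synthetic EEG cohorts with known ground truth. The generator emulates the
# structure the frequency-tagging analysis assumes: sinusoidal steady-state
# components phase-locked to trial onsets, a slow positive ERP-like transient
# after each tone, 1/f background noise per channel, and occasional
# high-amplitude artifact bursts, with per-subject amplitudes drawn from
# group-level distributions.

#' 1/f ("pink") noise
#'
#' Zero-mean noise whose power spectral density is proportional to
#' `1/f^exponent`, generated by shaping white Gaussian noise in the frequency
#' domain. The output is normalized to unit standard deviation; multiply by
#' the desired level in microvolts.
#'
#' @param n_samples Number of samples (>= 2).
#' @param exponent Spectral exponent (0 = white, 1 = pink).
#' @param rate_hz Sampling rate (sets the frequency axis only).
#' @param seed Optional integer; when given the sequence is reproducible.
#' @return Numeric vector of length `n_samples`.
#' @export
pink_noise <- function(n_samples, exponent = 1, rate_hz = 1000,
                       seed = NULL) {
  n <- assert_count(n_samples, "n_samples", min = 2L)
  assert_scalar_num(exponent, "exponent", lower = 0)
  gen <- function() {
    w <- rnorm(n)
    X <- fft(w)
    f <- c(1, seq_len(n - 1)) * rate_hz / n   # guard DC, zeroed below
    X <- X * f^(-exponent / 2)
    X[1] <- 0
    x <- Re(fft(X, inverse = TRUE)) / n
    x <- x - mean(x)
    x / sd(x)
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}

#' Noise level preserving measurement precision in a scaled-down cohort
#'
#' The standard error of a channel-averaged, trial-averaged SS-EP amplitude
#' scales as `noise / sqrt(n_trials * n_channels)`. When a simulation study
#' is run at a reduced trial and channel budget, dividing the background
#' noise level by `sqrt(budget_ratio)` keeps each subject's measurement
#' precision equal to that of the full-scale acquisition (32 trials, 124
#' channels by default), so group-level power reflects the full-scale study
#' rather than the reduced compute budget. Type-I error calibration is
#' unaffected by the noise level.
#'
#' @param base_level_uv Noise level of the full-scale acquisition (µV).
#' @param n_trials,n_channels The reduced budget.
#' @param base_trials,base_channels The full-scale budget.
#' @return Scaled noise level in µV.
#' @export
scaled_noise_level <- function(base_level_uv, n_trials, n_channels,
                               base_trials = 32, base_channels = 124) {
  base_level_uv / sqrt((base_trials * base_channels) /
                         (n_trials * n_channels))
}

#' Cohort simulation configuration
#'
#' Bundles every constant the generator needs. The `exp1` preset emulates the
#' 7-month-old study conditions: the six-beat ambiguous pattern, 17
#' repetitions per 34 s trial, 32 trials, components at 1, 1.5, 2, 2.5 and
#' 3 Hz, groups of 13 infants with and 46 without music classes, and a
#' selective duple-frequency (1.5 Hz) amplitude boost in the music-class
#' group. The `exp2` preset emulates the 15-month-old conditions: the
#' twelve-slot quadruple pattern, 9 repetitions per 36 s trial, 14 trials,
#' components at 0.75, 1.5 and 3 Hz, parent-trained (n = 16) vs untrained
#' (n = 17) groups, and an overall amplitude scaling for the trained group.
#' Any field can be overridden through `...`.
#'
#' @param preset `"exp1"`, `"exp2"` or `"custom"`.
#' @param ... Named overrides of any config field.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(preset = c("exp1", "exp2", "custom"), ...) {
  preset <- match.arg(preset)
  base <- list(
    preset = preset,
    pattern = pattern_sixbeat(),
    reps_per_trial = 17L,
    n_trials = 32L,
    n_channels = 32L,
    rate_hz = 1000,
    ssep_mean_uv = c("1" = 0.45, "1.5" = 0.5, "2" = 0.25,
                     "2.5" = 0.2, "3" = 0.4),
    ssep_sd_uv = 0.15,
    erp_amp_uv = 8,
    erp_latency_ms = 175,
    erp_width_ms = 160,
    noise_exponent = 1,
    noise_level_uv = 20,
    artifact_rate_per_trial = 0.5,
    artifact_amp_uv = 400,
    artifact_dur_ms = 200,
    groups = list(
      list(name = "music_class", n = 13L, music_classes = TRUE,
           parent_trained = FALSE),
      list(name = "no_class", n = 46L, music_classes = FALSE,
           parent_trained = FALSE)),
    effect = list(type = "duple_boost", factor = 1.8, target_hz = 1.5),
    age_months_mean = 7.2,
    seed = 20260101
  )
  if (preset == "exp2") {
    base$pattern <- pattern_twelvebeat()
    base$reps_per_trial <- 9L
    base$n_trials <- 14L
    base$ssep_mean_uv <- c("0.75" = 0.6, "1.5" = 0.35, "3" = 0.45)
    base$groups <- list(
      list(name = "parent_trained", n = 16L, music_classes = FALSE,
           parent_trained = TRUE),
      list(name = "parent_untrained", n = 17L, music_classes = FALSE,
           parent_trained = FALSE))
    base$effect <- list(type = "overall_boost", factor = 1.4,
                        target_hz = NA_real_)
    base$age_months_mean <- 15.45
  }
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(base))
  if (length(unknown) > 0) {
    abort(paste0("Unknown cohort_config field(s): ",
                 paste(unknown, collapse = ", ")))
  }
  # wholesale replacement (modifyList would skip unnamed list fields)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  validate_cohort_config(base)
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg$pattern, "rhythm_pattern"))
  cfg$reps_per_trial <- assert_count(cfg$reps_per_trial, "reps_per_trial")
  cfg$n_trials <- assert_count(cfg$n_trials, "n_trials")
  cfg$n_channels <- assert_count(cfg$n_channels, "n_channels", min = 2L)
  assert_scalar_num(cfg$rate_hz, "rate_hz", lower = 0, allow_zero = FALSE)
  if (is.null(names(cfg$ssep_mean_uv)) || any(cfg$ssep_mean_uv < 0)) {
    abort("`ssep_mean_uv` must be a named vector of non-negative amplitudes.")
  }
  assert_scalar_num(cfg$ssep_sd_uv, "ssep_sd_uv", lower = 0)
  assert_scalar_num(cfg$noise_level_uv, "noise_level_uv", lower = 0)
  for (g in cfg$groups) {
    if (is.null(g$n) || g$n < 1) abort("Each group needs n >= 1 subjects.")
  }
  if (!cfg$effect$type %in% c("none", "duple_boost", "overall_boost")) {
    abort("`effect$type` must be none, duple_boost or overall_boost.")
  }
  class(cfg) <- "cohort_config"
  cfg
}

trial_duration_s <- function(cfg) {
  cfg$reps_per_trial * pattern_duration(cfg$pattern)
}

# Tone-onset sample offsets (1-based, within one trial) and slot codes.
trial_tone_onsets <- function(cfg) {
  n_slots <- length(cfg$pattern$onset_flags)
  slots <- which(cfg$pattern$onset_flags == 1)
  reps <- seq_len(cfg$reps_per_trial)
  grid <- expand.grid(slot = slots, rep = reps)
  onset <- round_half_up(((grid$rep - 1) * n_slots + (grid$slot - 1)) *
                           cfg$pattern$ioi_seconds * cfg$rate_hz) + 1L
  arrange(tibble(sample = as.integer(onset),
                 code = paste0("tone_s", grid$slot)),
          .data$sample)
}

# Smooth zero-mean scalp gain profile with unit mean absolute value, so the
# channel-averaged spectral amplitude of a component equals its true
# amplitude and common-average referencing leaves it unchanged.
component_topography <- function(n_channels, index, n_components) {
  g <- cos(2 * pi * (seq_len(n_channels) - 1) / n_channels +
             2 * pi * (index - 1) / max(n_components, 1) + 0.7)
  g <- g - mean(g)
  g / mean(abs(g))
}

# Frontal-weighted zero-mean profile scaled so the mean over the frontal row
# is exactly 1 (ERP ground truth is expressed in frontal-group microvolts).
erp_topography <- function(n_channels) {
  w <- cos(pi * montage_depth(n_channels))
  w <- w - mean(w)
  frontal <- grepl("^F", montage_labels(n_channels))
  w / mean(w[frontal])
}

apply_group_effect <- function(means, effect, meta) {
  if (is.null(meta) || effect$type == "none") return(means)
  if (effect$type == "duple_boost" && isTRUE(meta$music_classes)) {
    key <- which.min(abs(as.numeric(names(means)) - effect$target_hz))
    means[key] <- means[key] * effect$factor
  } else if (effect$type == "overall_boost" && isTRUE(meta$parent_trained)) {
    means <- means * effect$factor
  }
  means
}

#' Simulate one subject's EEG recording with ground truth
#'
#' The recording is the sum of (i) sinusoids at each configured frequency,
#' phase-locked to trial onsets, with per-subject amplitudes drawn from the
#' (group-adjusted) normal distribution truncated at zero and a smooth
#' zero-mean scalp topography; (ii) a half-cosine positive transient after
#' every tone onset, frontal-weighted; (iii) per-channel 1/f noise; and (iv)
#' Poisson-placed artifact bursts. Events mark trial starts (`trial_start`)
#' and tone onsets (`tone_s<slot>`).
#'
#' @param config A [cohort_config()].
#' @param meta Optional one-row subject metadata (list or tibble row) with
#'   `music_classes` / `parent_trained` flags; `NULL` applies no group effect.
#' @param seed Integer seed; the recording is a pure function of
#'   (config, meta, seed).
#' @return List with `recording` ([eeg_recording()]) and `truth` (list with
#'   `ssep_amp_uv`, `erp_amp_uv`, `erp_latency_ms`, `noise_level_uv`).
#' @export
simulate_subject <- function(config, meta = NULL, seed = 1) {
  cfg <- validate_cohort_config(config)
  withr::with_seed(as.integer(seed) %% 2147483647L, {
    rate <- cfg$rate_hz
    trial_n <- round_half_up(trial_duration_s(cfg) * rate)
    total_n <- cfg$n_trials * trial_n
    nch <- cfg$n_channels
    labels <- montage_labels(nch)

    means <- apply_group_effect(cfg$ssep_mean_uv, cfg$effect, meta)
    amps <- pmax(0, rnorm(length(means), means, cfg$ssep_sd_uv))
    names(amps) <- names(means)

    # deterministic per-trial template: SS-EP sinusoids + ERP transients
    t_local <- (seq_len(trial_n) - 1) / rate
    onsets <- trial_tone_onsets(cfg)
    erp_trial <- numeric(trial_n)
    if (cfg$erp_amp_uv > 0) {
      w_n <- round_half_up(cfg$erp_width_ms / 1000 * rate)
      lat_n <- round_half_up(cfg$erp_latency_ms / 1000 * rate)
      rel <- seq(-floor(w_n / 2), floor(w_n / 2))
      bump <- cos(pi * rel / w_n)   # half-cosine, peak 1 at centre
      for (o in onsets$sample) {
        idx <- o + lat_n + rel
        ok <- idx >= 1 & idx <= trial_n
        erp_trial[idx[ok]] <- erp_trial[idx[ok]] + cfg$erp_amp_uv * bump[ok]
      }
    }

    data <- matrix(0, nch, total_n)
    freqs <- as.numeric(names(amps))
    for (k in seq_along(freqs)) {
      if (amps[k] == 0) next
      comp_trial <- amps[k] * sin(2 * pi * freqs[k] * t_local)
      comp <- rep(comp_trial, cfg$n_trials)
      data <- data + outer(component_topography(nch, k, length(freqs)), comp)
    }
    if (cfg$erp_amp_uv > 0) {
      data <- data + outer(erp_topography(nch), rep(erp_trial, cfg$n_trials))
    }
    if (cfg$noise_level_uv > 0) {
      for (ch in seq_len(nch)) {
        data[ch, ] <- data[ch, ] +
          cfg$noise_level_uv * pink_noise(total_n, cfg$noise_exponent, rate)
      }
    }
    if (cfg$artifact_rate_per_trial > 0 && cfg$artifact_amp_uv > 0) {
      n_art <- rpois(1, cfg$artifact_rate_per_trial * cfg$n_trials)
      dur_n <- max(1L, round_half_up(cfg$artifact_dur_ms / 1000 * rate))
      for (a in seq_len(n_art)) {
        ch <- sample.int(nch, 1)
        start <- sample.int(max(1L, total_n - dur_n), 1)
        idx <- start:(start + dur_n - 1L)
        data[ch, idx] <- data[ch, idx] +
          sample(c(-1, 1), 1) * cfg$artifact_amp_uv
      }
    }

    trial_starts <- tibble(
      sample = as.integer((seq_len(cfg$n_trials) - 1) * trial_n + 1L),
      code = "trial_start")
    tone_events <- purrr::map_dfr(seq_len(cfg$n_trials), function(tr) {
      tibble(sample = as.integer(onsets$sample + (tr - 1) * trial_n),
             code = onsets$code)
    })
    events <- arrange(bind_rows(trial_starts, tone_events), .data$sample)

    list(
      recording = eeg_recording(data, rate, labels, events),
      truth = list(ssep_amp_uv = amps,
                   erp_amp_uv = cfg$erp_amp_uv,
                   erp_latency_ms = cfg$erp_latency_ms,
                   noise_level_uv = cfg$noise_level_uv))
  })
}

#' Simulate a cohort of subjects with metadata
#'
#' Per-subject seeds are derived deterministically from the master seed in
#' `config$seed`, so an identical config reproduces the identical cohort.
#' Metadata (music-class flag, combined years of parent music training,
#' weekly music-listening hours, age) are drawn per subject; the group effect
#' configured in `config$effect` is applied inside [simulate_subject()].
#'
#' For full-size cohorts the raw recordings are large; supply `process` to
#' map each subject's `(recording, truth, meta)` to a reduced result (for
#' example the SS-EP amplitude table) that is stored instead of the
#' recording.
#'
#' @param config A [cohort_config()] with at least 2 subjects per group for
#'   downstream statistics.
#' @param process Optional `function(recording, truth, meta)`; its value is
#'   stored in place of the recording.
#' @return List with `meta` (tibble, one row per subject) and `subjects`
#'   (list of per-subject results).
#' @export
simulate_cohort <- function(config, process = NULL) {
  cfg <- validate_cohort_config(config)
  if (any(vapply(cfg$groups, function(g) g$n, numeric(1)) < 2)) {
    abort("Each group needs >= 2 subjects for group statistics.")
  }
  meta <- withr::with_seed(as.integer(cfg$seed) %% 2147483647L, {
    purrr::map_dfr(cfg$groups, function(g) {
      tibble(
        group = g$name,
        music_classes = isTRUE(g$music_classes),
        parent_trained = isTRUE(g$parent_trained),
        parent_training_years = if (isTRUE(g$parent_trained)) {
          round(runif(g$n, 5, 15), 1)
        } else {
          round(runif(g$n, 0, 4.9), 1)
        },
        listening_hours = round(runif(g$n, 1, 20), 1),
        age_months = round(rnorm(g$n, cfg$age_months_mean, 0.8), 2))
    })
  })
  meta <- mutate(meta,
                 subject_id = sprintf("S%03d", seq_len(nrow(meta))),
                 .before = 1)
  subjects <- purrr::map(seq_len(nrow(meta)), function(i) {
    sub <- simulate_subject(cfg, meta[i, ], seed = derive_seed(cfg$seed, i))
    if (is.null(process)) {
      c(list(meta = meta[i, ]), sub)
    } else {
      list(meta = meta[i, ],
           result = process(sub$recording, sub$truth, meta[i, ]),
           truth = sub$truth)
    }
  })
  list(meta = meta, subjects = subjects)
}
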