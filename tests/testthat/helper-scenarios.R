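# Shared simulation scenarios, scaled for the test budget. Group-level
# scenarios run at 2 trials x 8 channels x 500 Hz with the background-noise
# level reduced by scaled_noise_level() so per-subject measurement precision
# matches the full-scale acquisition (32 trials x 124 channels); SS-EP
# scenarios switch the ERP transient off so tagged-bin amplitudes equal the
# sinusoidal ground truth. The analysis epoch retains 1000-33000 ms (32 s),
# putting every tagged frequency exactly on a DFT bin.

.cache <- new.env(parent = emptyenv())

exp1_freqset <- function() {
  if (is.null(.cache$fs1)) {
    .cache$fs1 <- frequencies_of_interest(
      stimulus_spectrum(pattern_sixbeat(), repetitions = 17))
  }
  .cache$fs1
}

exp2_freqset <- function() {
  if (is.null(.cache$fs2)) {
    .cache$fs2 <- frequencies_of_interest(
      stimulus_spectrum(pattern_twelvebeat(), repetitions = 9))
  }
  .cache$fs2
}

scaled_exp1_config <- function(seed, n_per_group = c(8L, 8L),
                               effect_factor = 1.8, n_trials = 2L,
                               n_channels = 8L, rate_hz = 500, ...) {
  cohort_config(
    "exp1", seed = seed, n_trials = n_trials, n_channels = n_channels,
    rate_hz = rate_hz, erp_amp_uv = 0,
    noise_level_uv = scaled_noise_level(20, n_trials, n_channels),
    effect = list(type = if (effect_factor == 1) "none" else "duple_boost",
                  factor = effect_factor, target_hz = 1.5),
    groups = list(
      list(name = "music_class", n = n_per_group[1], music_classes = TRUE,
           parent_trained = FALSE),
      list(name = "no_class", n = n_per_group[2], music_classes = FALSE,
           parent_trained = FALSE)),
    ...)
}

# SS-EP analysis of one raw recording on the bin-aligned 32 s window.
ssep_process <- function(freqset, epoch_end_ms = 33000) {
  function(recording, truth, meta) {
    pre <- preprocess_recording(recording)
    avg <- epoch_average(pre, trial_onsets(pre), 0, epoch_end_ms,
                         baseline_start_ms = 900, baseline_end_ms = 1000,
                         discard_first_ms = 1000)
    ssep_subject(avg, freqset, subject_id = meta$subject_id)
  }
}

# Simulate a cohort and return metadata joined to SS-EP amplitudes.
ssep_cohort_table <- function(config, freqset) {
  cohort <- simulate_cohort(config, process = ssep_process(freqset))
  dplyr::left_join(cohort$meta,
                   purrr::map_dfr(cohort$subjects, function(s) s$result),
                   by = "subject_id")
}

# Group x frequency interaction p-values (uncorrected and GG) of a cohort.
interaction_p <- function(cohort_table, freqs = c(1, 1.5, 2, 2.5, 3)) {
  cols <- paste0("ssep_", vapply(freqs, format, character(1)))
  long <- tidyr::pivot_longer(
    dplyr::select(cohort_table, dplyr::all_of(c("subject_id",
                                                "music_classes", cols))),
    dplyr::all_of(cols), names_to = "frequency", values_to = "amplitude")
  tb <- tidy(mixed_anova_gg(long, "amplitude", "subject_id",
                            "music_classes", "frequency"))
  c(raw = tb$p[tb$effect == "interaction"],
    gg = tb$p_gg[tb$effect == "interaction"])
}

# Stats-layer null cohort: per-subject tagged amplitudes drawn directly from
# the no-effect group distribution (no EEG simulation).
stats_null_interaction_p <- function(n_per_group = 8) {
  means <- c(0.45, 0.5, 0.25, 0.2, 0.4)
  n <- 2 * n_per_group
  Y <- t(replicate(n, pmax(0, rnorm(5, means, 0.15))))
  long <- long_from_matrix(Y, rep(c("a", "b"), each = n_per_group))
  tb <- tidy(mixed_anova_gg(long, "value", "subject_id", "grp", "level"))
  c(raw = tb$p[tb$effect == "interaction"],
    gg = tb$p_gg[tb$effect == "interaction"])
}
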