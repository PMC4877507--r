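# Steady-state evoked-potential extraction: per-channel spectra of the
# averaged waveform, neighbour-bin noise subtraction, channel averaging,
# 3-bin peak picking and the noise-floor / outlier statistics.

#' Per-channel amplitude spectra of an averaged waveform
#'
#' One single-sided, amplitude-calibrated spectrum per channel; the frequency
#' resolution is the reciprocal of the averaged-epoch duration.
#'
#' @param avg An `averaged_waveform` of at least 4 s duration.
#' @return A `channel_spectra` tibble with columns `channel`,
#'   `frequency_hz`, `amplitude` and attributes `resolution_hz`,
#'   `noise_corrected = FALSE`.
#' @export
spectrum_per_channel <- function(avg) {
  stopifnot(inherits(avg, "averaged_waveform"))
  dur <- ncol(avg$data) / avg$rate_hz
  if (dur < 4) {
    abort(sprintf("Waveform too short for SS-EP analysis (%.3g s < 4 s).",
                  dur))
  }
  res <- 1 / dur
  out <- purrr::map_dfr(seq_len(nrow(avg$data)), function(ch) {
    a <- single_sided_amplitude(avg$data[ch, ])
    tibble(channel = avg$channel_labels[ch],
           frequency_hz = (seq_along(a) - 1) * res,
           amplitude = a)
  })
  class(out) <- c("channel_spectra", class(out))
  attr(out, "resolution_hz") <- res
  attr(out, "noise_corrected") <- FALSE
  out
}

#' Per-subject SS-EP amplitude summary
#'
#' Runs the full SS-EP stage on one subject's averaged waveform: per-channel
#' spectra, neighbour-bin noise subtraction, channel averaging, then 3-bin
#' peak amplitudes at every stimulus-present frequency and the noise floor
#' over the stimulus-absent frequencies.
#'
#' @param avg An `averaged_waveform`.
#' @param freqset A `frequency_set` (see [frequencies_of_interest()]).
#' @param subject_id Identifier carried into the output row.
#' @param band_bins Peak-picking band width in bins.
#' @return A one-row tibble: `subject_id`, one `ssep_<freq>` column per
#'   stimulus-present frequency (channel-averaged, noise-subtracted µV) and
#'   `noise_floor`.
#' @export
ssep_subject <- function(avg, freqset, subject_id = "S001", band_bins = 3) {
  stopifnot(inherits(freqset, "frequency_set"))
  spec <- avg |>
    spectrum_per_channel() |>
    subtract_noise() |>
    average_across_channels()
  amps <- vapply(freqset$stimulus_present_hz,
                 function(f) peak_amplitude(spec, f, band_bins), numeric(1))
  row <- tibble(subject_id = subject_id)
  for (i in seq_along(amps)) {
    row[[paste0("ssep_", format(freqset$stimulus_present_hz[i]))]] <- amps[i]
  }
  row$noise_floor <- noise_floor(spec, freqset$stimulus_absent_hz, band_bins)
  row
}

#' Flag outlying subjects by z-score
#'
#' Standardizes the per-subject scores (typically the mean SS-EP amplitude
#' across the tagged frequencies) and marks subjects whose absolute z-score
#' exceeds the cutoff for exclusion. With zero variance all subjects are
#' kept.
#'
#' @param scores Numeric vector, one score per subject (>= 3 subjects).
#' @param cutoff Absolute z-score beyond which a subject is excluded.
#' @return Logical inclusion mask (`TRUE` = keep).
#' @export
zscore_exclude <- function(scores, cutoff = 3) {
  if (length(scores) < 3) abort("Outlier screening needs >= 3 subjects.")
  s <- sd(scores)
  if (s == 0) return(rep(TRUE, length(scores)))
  abs((scores - mean(scores)) / s) <= cutoff
}

#' SS-EP columns of a cohort table
#'
#' @param cohort_table A tibble with `ssep_<freq>` columns.
#' @return Character vector of the SS-EP amplitude column names.
#' @export
ssep_columns <- function(cohort_table) {
  grep("^ssep_", names(cohort_table), value = TRUE)
}
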