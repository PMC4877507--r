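# Amplitude spectra and the frequency-domain operations shared by the
# stimulus-envelope and SS-EP analyses.

new_amp_spectrum <- function(frequency_hz, amplitude, resolution_hz,
                             noise_corrected) {
  out <- tibble(frequency_hz = frequency_hz, amplitude = amplitude)
  class(out) <- c("amp_spectrum", class(out))
  attr(out, "resolution_hz") <- resolution_hz
  attr(out, "noise_corrected") <- noise_corrected
  out
}

single_sided_amplitude <- function(x) {
  n <- length(x)
  a <- Mod(fft(x)) / n
  half <- floor(n / 2) + 1L
  a <- a[seq_len(half)]
  if (half > 2L) {
    last_double <- if (n %% 2 == 0) half - 1L else half
    a[2:last_double] <- 2 * a[2:last_double]
  }
  a
}

#' Single-sided amplitude spectrum of a signal
#'
#' Discrete Fourier transform scaled so that a sinusoid of amplitude A whose
#' frequency falls exactly on a bin yields amplitude A at that bin (and a
#' constant signal c yields c at DC). The frequency resolution is the
#' reciprocal of the signal duration.
#'
#' @param signal An [audio_signal()] (or numeric vector via `rate_hz`).
#' @param rate_hz Sampling rate, required when `signal` is a bare vector.
#' @return An `amp_spectrum` tibble with columns `frequency_hz`, `amplitude`
#'   and attributes `resolution_hz`, `noise_corrected = FALSE`.
#' @examples
#' env <- hilbert_envelope(synthesize(pattern_sixbeat(), 8000, 17))
#' sp <- amplitude_spectrum(resample_audio(env, 200))
#' @export
amplitude_spectrum <- function(signal, rate_hz = NULL) {
  if (inherits(signal, "audio_signal")) {
    x <- signal$samples
    rate_hz <- signal$rate_hz
  } else {
    if (is.null(rate_hz)) abort("`rate_hz` is required for a bare vector.")
    x <- as.numeric(signal)
  }
  if (length(x) == 0) abort("Cannot take the spectrum of an empty signal.")
  res <- rate_hz / length(x)
  a <- single_sided_amplitude(x)
  new_amp_spectrum((seq_along(a) - 1) * res, a, res, noise_corrected = FALSE)
}

spectrum_resolution <- function(spectrum) attr(spectrum, "resolution_hz")

is_noise_corrected <- function(spectrum) {
  isTRUE(attr(spectrum, "noise_corrected"))
}

# Nearest bin index (1-based) for a target frequency; an exact midpoint
# between two bins resolves to the lower-frequency bin.
nearest_bin <- function(target_hz, resolution_hz, n_bins, start_hz = 0) {
  pos <- (target_hz - start_hz) / resolution_hz
  k <- floor(pos)
  frac <- pos - k
  idx <- if (frac <= 0.5 + 1e-12) k else k + 1
  idx <- as.integer(idx) + 1L
  if (idx < 1L || idx > n_bins) {
    abort(sprintf("Frequency %g Hz is outside the spectrum range.", target_hz))
  }
  idx
}

#' Subtract the local noise floor from an amplitude spectrum
#'
#' Each bin has the mean amplitude of its neighbouring bins subtracted; the
#' neighbourhood is the bins at offsets -`high`..-`low` and +`low`..+`high`
#' (default -5..-3 and +3..+5, i.e. 0.09-0.15 Hz away at ~0.03 Hz
#' resolution). Because the neighbourhood is symmetric, any locally linear
#' background cancels exactly; corrected amplitudes may be negative and are
#' deliberately not clipped so that noise-only spectra stay centred on zero.
#' Bins closer than `offset_bins_high` to either edge cannot be corrected and
#' are set to `NA`.
#'
#' @param spectrum An uncorrected `amp_spectrum` or `channel_spectra` object.
#' @param offset_bins_low,offset_bins_high Inner and outer neighbour offsets
#'   in bins.
#' @return The same type of object, flagged `noise_corrected`.
#' @export
subtract_noise <- function(spectrum, offset_bins_low = 3,
                           offset_bins_high = 5) {
  if (is_noise_corrected(spectrum)) {
    abort("Spectrum is already noise-corrected.")
  }
  lo <- assert_count(offset_bins_low, "offset_bins_low")
  hi <- assert_count(offset_bins_high, "offset_bins_high")
  if (hi < lo) abort("`offset_bins_high` must be >= `offset_bins_low`.")
  correct_one <- function(a) {
    n <- length(a)
    if (n <= 2 * hi) abort("Spectrum too short for the neighbour offsets.")
    offs <- c(-(hi:lo), lo:hi)
    corrected <- rep(NA_real_, n)
    valid <- (hi + 1L):(n - hi)
    neigh <- vapply(offs, function(o) a[valid + o], numeric(length(valid)))
    corrected[valid] <- a[valid] - rowMeans(neigh)
    corrected
  }
  if (inherits(spectrum, "channel_spectra")) {
    out <- spectrum |>
      group_by(.data$channel) |>
      mutate(amplitude = correct_one(.data$amplitude)) |>
      ungroup()
    class(out) <- class(spectrum)
  } else {
    out <- spectrum
    out$amplitude <- correct_one(out$amplitude)
  }
  attr(out, "resolution_hz") <- spectrum_resolution(spectrum)
  attr(out, "noise_corrected") <- TRUE
  out
}

#' Average amplitude spectra across channels
#'
#' Bin-wise arithmetic mean over channels, used to obtain one spectrum per
#' participant without selecting electrodes.
#'
#' @param spectra A `channel_spectra` tibble (columns `channel`,
#'   `frequency_hz`, `amplitude`) with a common bin grid across channels.
#' @return An `amp_spectrum` tibble.
#' @export
average_across_channels <- function(spectra) {
  if (!inherits(spectra, "channel_spectra")) {
    abort("`spectra` must be a channel_spectra object.")
  }
  grids <- spectra |>
    group_by(.data$channel) |>
    summarise(n = dplyr::n(), f1 = .data$frequency_hz[1])
  if (length(unique(grids$n)) != 1 || length(unique(grids$f1)) != 1) {
    abort("Channels have mismatched bin grids.")
  }
  out <- spectra |>
    group_by(.data$frequency_hz) |>
    summarise(amplitude = mean(.data$amplitude)) |>
    arrange(.data$frequency_hz)
  new_amp_spectrum(out$frequency_hz, out$amplitude,
                   spectrum_resolution(spectra),
                   is_noise_corrected(spectra))
}

#' Peak amplitude in a narrow band around a target frequency
#'
#' The maximum amplitude over a `band_bins`-wide band centred on the bin
#' nearest the target frequency (default 3 bins: nearest bin and its two
#' neighbours). When the target falls exactly midway between two bins the
#' lower-frequency bin is taken as centre.
#'
#' @param spectrum An `amp_spectrum`.
#' @param target_hz Frequency of interest in Hz.
#' @param band_bins Odd band width in bins.
#' @return The peak amplitude (may be negative for corrected spectra).
#' @export
peak_amplitude <- function(spectrum, target_hz, band_bins = 3) {
  band_bins <- assert_count(band_bins, "band_bins")
  if (band_bins %% 2 == 0) abort("`band_bins` must be odd.")
  res <- spectrum_resolution(spectrum)
  n <- nrow(spectrum)
  centre <- nearest_bin(target_hz, res, n, spectrum$frequency_hz[1])
  half <- (band_bins - 1L) / 2L
  idx <- (centre - half):(centre + half)
  if (any(idx < 1L | idx > n)) {
    abort(sprintf("Band around %g Hz extends beyond the spectrum.", target_hz))
  }
  vals <- spectrum$amplitude[idx]
  if (anyNA(vals)) {
    abort(sprintf("Band around %g Hz touches uncorrected edge bins.",
                  target_hz))
  }
  max(vals)
}

#' Average noise-floor amplitude over stimulus-absent frequencies
#'
#' The mean of [peak_amplitude()] evaluated at each frequency where the
#' stimulus contains no energy.
#'
#' @param spectrum An `amp_spectrum` (normally noise-corrected).
#' @param absent_hz Numeric vector of stimulus-absent frequencies.
#' @param band_bins Band width passed to [peak_amplitude()].
#' @return Mean amplitude across the absent frequencies.
#' @export
noise_floor <- function(spectrum, absent_hz, band_bins = 3) {
  if (length(absent_hz) == 0) abort("`absent_hz` must be nonempty.")
  mean(vapply(absent_hz, function(f) peak_amplitude(spectrum, f, band_bins),
              numeric(1)))
}

#' Derive beat/meter frequencies of interest from a stimulus spectrum
#'
#' Scans the uncorrected envelope spectrum for bins in `band_hz` whose
#' amplitude exceeds `energy_threshold` times the in-band maximum; these are
#' the stimulus-present frequencies (after dropping `exclude_hz`, e.g. the
#' 0.5 Hz bin removed by the high-pass filter). The stimulus-absent control
#' frequencies are the midpoints between consecutive detected harmonics.
#'
#' @param stim_spectrum Uncorrected `amp_spectrum` of the stimulus envelope.
#' @param band_hz Length-2 numeric, analysis band in Hz.
#' @param exclude_hz Frequencies removed from the present set.
#' @param energy_threshold Fraction of the in-band maximum amplitude a bin
#'   must exceed to count as stimulus energy.
#' @param beat_hz Beat frequency in Hz.
#' @param groupings Named integer vector of metrical groupings.
#' @return A `frequency_set`: list with `beat_hz`, named `meter_hz`,
#'   `stimulus_present_hz` and `stimulus_absent_hz` (sorted, disjoint).
#' @export
frequencies_of_interest <- function(stim_spectrum, band_hz = c(0.5, 3),
                                    exclude_hz = 0.5,
                                    energy_threshold = 0.02,
                                    beat_hz = 3,
                                    groupings = c(duple = 2, triple = 3,
                                                  quadruple = 4)) {
  if (is_noise_corrected(stim_spectrum)) {
    abort("`stim_spectrum` must be uncorrected.")
  }
  if (length(band_hz) != 2 || band_hz[2] <= band_hz[1]) {
    abort("`band_hz` must be an increasing length-2 interval.")
  }
  if (band_hz[2] > max(stim_spectrum$frequency_hz)) {
    abort("`band_hz` extends beyond the spectrum range.")
  }
  tol <- spectrum_resolution(stim_spectrum) / 2
  in_band <- stim_spectrum$frequency_hz >= band_hz[1] - tol &
    stim_spectrum$frequency_hz <= band_hz[2] + tol
  amps <- stim_spectrum$amplitude[in_band]
  freqs <- stim_spectrum$frequency_hz[in_band]
  candidates <- freqs[amps > energy_threshold * max(amps, 0)]
  near_any <- function(x, set) {
    if (length(set) == 0) return(rep(FALSE, length(x)))
    vapply(x, function(f) any(abs(f - set) < tol), logical(1))
  }
  present <- candidates[!near_any(candidates, exclude_hz)]
  absent <- if (length(candidates) >= 2) {
    (head(candidates, -1) + tail(candidates, -1)) / 2
  } else {
    numeric(0)
  }
  structure(
    list(beat_hz = beat_hz,
         meter_hz = beat_hz / groupings,
         stimulus_present_hz = sort(present),
         stimulus_absent_hz = sort(absent)),
    class = "frequency_set")
}

#' @export
print.frequency_set <- function(x, ...) {
  cat("<frequency_set>\n")
  cat("  beat:   ", x$beat_hz, "Hz\n")
  cat("  meter:  ", paste(sprintf("%s %g Hz", names(x$meter_hz), x$meter_hz),
                          collapse = ", "), "\n")
  cat("  present:", paste(x$stimulus_present_hz, collapse = ", "), "\n")
  cat("  absent: ", paste(x$stimulus_absent_hz, collapse = ", "), "\n")
  invisible(x)
}

#' Stimulus envelope spectrum for a pattern
#'
#' Convenience chain: synthesize the pattern, extract the instantaneous
#' amplitude envelope, downsample it to the shared 200 Hz analysis rate and
#' take its amplitude spectrum. The window covers exactly `repetitions`
#' whole patterns, so envelope energy sits on the pattern-repetition harmonic
#' grid.
#'
#' @param pattern A [rhythm_pattern()].
#' @param repetitions Whole patterns in the analysis window.
#' @param rate_hz Audio synthesis rate.
#' @param envelope_rate_hz Rate of the envelope before its DFT.
#' @return An `amp_spectrum`.
#' @export
stimulus_spectrum <- function(pattern, repetitions = 17, rate_hz = 8000,
                              envelope_rate_hz = 200) {
  audio <- synthesize(pattern, rate_hz = rate_hz, repetitions = repetitions)
  env <- hilbert_envelope(audio)
  amplitude_spectrum(resample_audio(env, envelope_rate_hz))
}
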