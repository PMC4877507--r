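# Preprocessing chain: zero-phase band-pass -> resample -> artifact
# attenuation -> common-average reference -> epoch averaging. All operations
# preserve channel count, labels and (rate-remapped) events.

with_new_data <- function(recording, data, rate_hz = NULL, events = NULL) {
  eeg_recording(data, rate_hz %||% recording$rate_hz,
                recording$channel_labels, events %||% recording$events)
}

#' Zero-phase band-pass filter
#'
#' Removes each channel's mean, then applies 4th-order Butterworth high-pass
#' and low-pass filters forward and backward (`signal::filtfilt`), so the
#' net response is zero-phase — mandatory for phase-locked averaging. The
#' default corners are 0.5 and 20 Hz.
#'
#' @param recording An [eeg_recording()].
#' @param high_pass_hz,low_pass_hz Corner frequencies, `0 < hp < lp <
#'   rate/2`.
#' @param order Butterworth order of each filter (before the
#'   forward-backward doubling).
#' @return A filtered [eeg_recording()].
#' @export
eeg_bandpass <- function(recording, high_pass_hz = 0.5, low_pass_hz = 20,
                         order = 4) {
  stopifnot(inherits(recording, "eeg_recording"))
  nyq <- recording$rate_hz / 2
  if (!(high_pass_hz > 0 && high_pass_hz < low_pass_hz &&
        low_pass_hz < nyq)) {
    abort("Require 0 < high_pass_hz < low_pass_hz < rate/2.")
  }
  hp <- signal::butter(order, high_pass_hz / nyq, type = "high")
  lp <- signal::butter(order, low_pass_hz / nyq, type = "low")
  data <- recording$data
  for (ch in seq_len(nrow(data))) {
    x <- data[ch, ] - mean(data[ch, ])
    data[ch, ] <- signal::filtfilt(lp, signal::filtfilt(hp, x))
  }
  with_new_data(recording, data)
}

#' Resample a recording to a lower rate
#'
#' Integer decimation factors use a zero-phase 8th-order Butterworth
#' anti-alias low-pass at 0.8x the new Nyquist followed by subsampling;
#' non-integer ratios use Fourier-domain resampling. Event indices are
#' remapped by the rate ratio with half-up rounding. In-band sinusoids are
#' preserved to well under 1%.
#'
#' @param recording An [eeg_recording()].
#' @param target_hz New sampling rate (must not exceed the original).
#' @return An [eeg_recording()] at `target_hz`.
#' @export
eeg_resample <- function(recording, target_hz = 200) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (target_hz > recording$rate_hz) {
    abort("Target rate exceeds the original rate.")
  }
  if (target_hz == recording$rate_hz) return(recording)
  data <- t(apply(recording$data, 1, resample_vector,
                  rate_from = recording$rate_hz, rate_to = target_hz))
  events <- recording$events
  events$sample <- remap_sample_index(events$sample, recording$rate_hz,
                                      target_hz)
  events$sample <- pmin(events$sample, ncol(data))
  with_new_data(recording, data, rate_hz = target_hz, events = events)
}

#' Attenuate high-amplitude artifact segments
#'
#' A simple threshold-based attenuator (a deliberately transparent stand-in
#' for more elaborate artifact-removal algorithms): on each channel, runs of
#' samples exceeding `threshold_uv` in magnitude are widened by a 10 ms guard
#' on each side and replaced by linear interpolation between the surrounding
#' clean samples.
#'
#' @param recording An [eeg_recording()].
#' @param threshold_uv Positive magnitude threshold in microvolts.
#' @param guard_ms Guard interval appended to each flagged run.
#' @return An [eeg_recording()] with flagged runs interpolated.
#' @export
attenuate_artifacts <- function(recording, threshold_uv = 200,
                                guard_ms = 10) {
  stopifnot(inherits(recording, "eeg_recording"))
  assert_scalar_num(threshold_uv, "threshold_uv", lower = 0,
                    allow_zero = FALSE)
  guard_n <- round_half_up(guard_ms / 1000 * recording$rate_hz)
  data <- recording$data
  n <- ncol(data)
  for (ch in seq_len(nrow(data))) {
    x <- data[ch, ]
    bad <- abs(x) > threshold_uv
    if (!any(bad)) next
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      i0 <- max(1L, starts[j] - guard_n)
      i1 <- min(n, ends[j] + guard_n)
      left <- if (i0 > 1L) x[i0 - 1L] else NA_real_
      right <- if (i1 < n) x[i1 + 1L] else NA_real_
      if (is.na(left) && is.na(right)) { left <- 0; right <- 0 }
      if (is.na(left)) left <- right
      if (is.na(right)) right <- left
      x[i0:i1] <- seq(left, right, length.out = i1 - i0 + 3L)[2:(i1 - i0 + 2L)]
    }
    data[ch, ] <- x
  }
  with_new_data(recording, data)
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the per-sample channel mean is zero.
#'
#' @param recording An [eeg_recording()] with at least two channels.
#' @return A re-referenced [eeg_recording()].
#' @export
rereference_common_average <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (n_channels(recording) < 2) {
    abort("Common-average referencing needs >= 2 channels.")
  }
  data <- sweep(recording$data, 2, colMeans(recording$data))
  with_new_data(recording, data)
}

new_averaged_waveform <- function(data, rate_hz, t0_ms, n_epochs,
                                  channel_labels) {
  rownames(data) <- channel_labels
  structure(list(data = data, rate_hz = rate_hz, t0_ms = t0_ms,
                 n_epochs_averaged = n_epochs,
                 channel_labels = channel_labels),
            class = "averaged_waveform")
}

#' @export
print.averaged_waveform <- function(x, ...) {
  cat(sprintf("<averaged_waveform> %d channels x %d samples @ %g Hz, t0 %g ms, %d epochs\n",
              nrow(x$data), ncol(x$data), x$rate_hz, x$t0_ms,
              x$n_epochs_averaged))
  invisible(x)
}

# Time axis of an averaged waveform, in ms relative to the epoch onset.
waveform_times_ms <- function(avg) {
  avg$t0_ms + (seq_len(ncol(avg$data)) - 1) / avg$rate_hz * 1000
}

#' Epoch and average a recording around onsets
#'
#' Per channel: epochs `[start_ms, end_ms)` are extracted relative to each
#' onset sample, each epoch has the mean of its baseline window
#' `[baseline_start_ms, baseline_end_ms)` subtracted, the epochs are
#' averaged, and finally the first `discard_first_ms` of the average is
#' removed (to drop onset transients). Onsets whose window would extend
#' beyond the recording are skipped with a warning; zero usable onsets is an
#' error.
#'
#' @param recording An [eeg_recording()].
#' @param onset_samples 1-based onset sample indices.
#' @param start_ms,end_ms Epoch window relative to onset, ms.
#' @param baseline_start_ms,baseline_end_ms Baseline window relative to
#'   onset, ms; `NULL` disables baseline correction.
#' @param discard_first_ms Initial portion of the averaged epoch to discard.
#' @return An `averaged_waveform` (channels x samples matrix plus rate,
#'   `t0_ms` and the number of epochs averaged).
#' @export
epoch_average <- function(recording, onset_samples, start_ms, end_ms,
                          baseline_start_ms = NULL, baseline_end_ms = NULL,
                          discard_first_ms = 0) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (length(onset_samples) < 1) abort("Need at least one onset.")
  if (end_ms <= start_ms) abort("`end_ms` must exceed `start_ms`.")
  rate <- recording$rate_hz
  n <- n_samples(recording)
  off0 <- round_half_up(start_ms / 1000 * rate)
  off1 <- round_half_up(end_ms / 1000 * rate) - 1L
  usable <- onset_samples[onset_samples + off0 >= 1 &
                            onset_samples + off1 <= n]
  skipped <- length(onset_samples) - length(usable)
  if (skipped > 0) {
    warn(sprintf("Skipped %d onset(s) too close to the recording edge.",
                 skipped))
  }
  if (length(usable) == 0) abort("No usable epochs inside the recording.")
  len <- off1 - off0 + 1L
  acc <- matrix(0, n_channels(recording), len)
  base_idx <- NULL
  if (!is.null(baseline_start_ms)) {
    b0 <- round_half_up(baseline_start_ms / 1000 * rate)
    b1 <- round_half_up(baseline_end_ms / 1000 * rate) - 1L
    if (b0 < off0 || b1 > off1 || b1 < b0) {
      abort("Baseline window must lie inside the epoch window.")
    }
    base_idx <- (b0 - off0 + 1L):(b1 - off0 + 1L)
  }
  for (o in usable) {
    ep <- recording$data[, (o + off0):(o + off1), drop = FALSE]
    if (!is.null(base_idx)) {
      ep <- ep - rowMeans(ep[, base_idx, drop = FALSE])
    }
    acc <- acc + ep
  }
  avg <- acc / length(usable)
  drop_n <- round_half_up(discard_first_ms / 1000 * rate)
  if (drop_n >= len) abort("`discard_first_ms` removes the whole epoch.")
  if (drop_n > 0) avg <- avg[, -(seq_len(drop_n)), drop = FALSE]
  new_averaged_waveform(avg, rate, start_ms + drop_n / rate * 1000,
                        length(usable), recording$channel_labels)
}

#' Trial-start onsets of a recording
#'
#' @param recording An [eeg_recording()] with `trial_start` events.
#' @return Integer vector of onset samples.
#' @export
trial_onsets <- function(recording) {
  recording$events$sample[recording$events$code == "trial_start"]
}

#' Run the standard preprocessing chain
#'
#' Band-pass (0.5-20 Hz) -> resample (200 Hz) -> artifact attenuation ->
#' common-average reference, in that order.
#'
#' @param recording An [eeg_recording()].
#' @param high_pass_hz,low_pass_hz,target_rate_hz,artifact_threshold_uv
#'   Chain constants.
#' @return A preprocessed [eeg_recording()].
#' @export
preprocess_recording <- function(recording, high_pass_hz = 0.5,
                                 low_pass_hz = 20, target_rate_hz = 200,
                                 artifact_threshold_uv = 200) {
  recording |>
    eeg_bandpass(high_pass_hz, low_pass_hz) |>
    eeg_resample(target_rate_hz) |>
    attenuate_artifacts(artifact_threshold_uv) |>
    rereference_common_average()
}
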