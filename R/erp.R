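# Transient evoked responses: epoching to tone onsets, frontal channel-group
# averaging, grand-average peak latency and area under the curve.

#' Select ERP onset samples from a recording's events
#'
#' Two selection rules are provided because "the first tone" of a pattern can
#' be read two ways: `"pattern_start"` takes the tone in slot 1 of every
#' pattern repetition; `"post_silence"` takes every tone whose preceding slot
#' (cyclically) is silent.
#'
#' @param recording An [eeg_recording()] with `tone_s<slot>` events.
#' @param pattern The [rhythm_pattern()] that generated the events.
#' @param rule `"pattern_start"` or `"post_silence"`.
#' @return Integer vector of onset samples.
#' @export
select_erp_onsets <- function(recording, pattern,
                              rule = c("pattern_start", "post_silence")) {
  rule <- match.arg(rule)
  flags <- pattern$onset_flags
  slots <- if (rule == "pattern_start") {
    if (flags[1] != 1) abort("Pattern does not start with a tone.")
    1L
  } else {
    which(flags == 1 &
            flags[c(length(flags), seq_len(length(flags) - 1))] == 0)
  }
  codes <- paste0("tone_s", slots)
  sort(recording$events$sample[recording$events$code %in% codes])
}

#' Epoch-average a recording around tone onsets for ERP analysis
#'
#' Epochs from `start_ms` to `end_ms` relative to each onset (defaults -100
#' to 300 ms) are averaged per channel with per-epoch baseline-mean
#' subtraction over the baseline window (default -100 to 0 ms).
#'
#' @param recording An [eeg_recording()].
#' @param tone_onsets 1-based onset sample indices (see
#'   [select_erp_onsets()]).
#' @param start_ms,end_ms Epoch window relative to onset.
#' @param baseline Length-2 numeric baseline window in ms.
#' @return An `averaged_waveform`.
#' @export
erp_epoch_average <- function(recording, tone_onsets, start_ms = -100,
                              end_ms = 300, baseline = c(-100, 0)) {
  epoch_average(recording, tone_onsets, start_ms, end_ms,
                baseline_start_ms = baseline[1],
                baseline_end_ms = baseline[2])
}

#' Mean waveform over a channel group
#'
#' @param avg An `averaged_waveform`.
#' @param channel_subset Character vector of channel labels (no duplicates).
#' @return An `averaged_waveform` with a single channel named `"group"`.
#' @export
channel_group_mean <- function(avg, channel_subset) {
  stopifnot(inherits(avg, "averaged_waveform"))
  if (length(channel_subset) == 0) abort("`channel_subset` is empty.")
  if (anyDuplicated(channel_subset)) {
    abort("`channel_subset` contains duplicate labels.")
  }
  missing <- setdiff(channel_subset, avg$channel_labels)
  if (length(missing) > 0) {
    abort(paste0("Unknown channel label(s): ",
                 paste(missing, collapse = ", ")))
  }
  idx <- match(channel_subset, avg$channel_labels)
  data <- matrix(colMeans(avg$data[idx, , drop = FALSE]), nrow = 1)
  new_averaged_waveform(data, avg$rate_hz, avg$t0_ms,
                        avg$n_epochs_averaged, "group")
}

#' Latency of the largest-magnitude peak in a grand average
#'
#' Returns the time (ms relative to epoch onset) of the maximum absolute
#' value inside the search window; ties break to the earliest sample. The
#' default window 50-300 ms avoids baseline edge effects.
#'
#' @param wave A single-channel `averaged_waveform` (e.g. a grand average
#'   over subjects and a channel group).
#' @param search_ms Length-2 search window in ms.
#' @return Peak latency in ms.
#' @export
grand_peak_latency <- function(wave, search_ms = c(50, 300)) {
  stopifnot(inherits(wave, "averaged_waveform"), nrow(wave$data) == 1)
  t_ms <- waveform_times_ms(wave)
  idx <- which(t_ms >= search_ms[1] & t_ms <= search_ms[2])
  if (length(idx) == 0) abort("Empty search window.")
  x <- abs(wave$data[1, idx])
  t_ms[idx[which.max(x)]]   # which.max returns the first (earliest) maximum
}

#' Area under the curve around a peak
#'
#' Signed trapezoidal integral of the (baseline-corrected) waveform over
#' `[center_ms - half_width_ms, center_ms + half_width_ms]`, in µV·ms.
#' Rectified area is available as an option.
#'
#' @param wave A single-channel `averaged_waveform`.
#' @param center_ms Centre of the integration window (ms).
#' @param half_width_ms Half-width of the window (ms).
#' @param rectify Integrate `|x|` instead of the signed waveform.
#' @return Area in µV·ms.
#' @export
area_under_curve <- function(wave, center_ms, half_width_ms = 50,
                             rectify = FALSE) {
  stopifnot(inherits(wave, "averaged_waveform"), nrow(wave$data) == 1)
  t_ms <- waveform_times_ms(wave)
  lo <- center_ms - half_width_ms
  hi <- center_ms + half_width_ms
  if (lo < t_ms[1] - 1e-9 || hi > t_ms[length(t_ms)] + 1e-9) {
    abort("Integration window is clipped by the epoch edge.")
  }
  idx <- which(t_ms >= lo - 1e-9 & t_ms <= hi + 1e-9)
  x <- wave$data[1, idx]
  if (rectify) x <- abs(x)
  tt <- t_ms[idx]
  sum(diff(tt) * (head(x, -1) + tail(x, -1)) / 2)
}

#' Per-subject ERP summary over frontal channel groups
#'
#' Epochs the recording to the selected tone onsets, averages the left and
#' right frontal channel groups, and integrates the area under the curve
#' around `center_ms` (normally the grand-average peak latency) for each
#' hemisphere.
#'
#' @param recording A preprocessed [eeg_recording()].
#' @param tone_onsets Onset samples (see [select_erp_onsets()]).
#' @param groups List with `left` and `right` character label vectors;
#'   default: the frontal row of the montage.
#' @param center_ms AUC window centre; a single value used for both
#'   hemispheres or a named vector `c(left = , right = )`.
#' @param half_width_ms AUC half-width.
#' @param subject_id Identifier carried into the output row.
#' @return One-row tibble: `subject_id`, `auc_left`, `auc_right` (µV·ms),
#'   `peak_latency_left`, `peak_latency_right` (ms).
#' @export
erp_subject <- function(recording, tone_onsets, groups = NULL,
                        center_ms = 175, half_width_ms = 50,
                        subject_id = "S001") {
  groups <- groups %||% frontal_groups(recording$channel_labels)
  avg <- erp_epoch_average(recording, tone_onsets)
  centers <- if (length(center_ms) == 2) center_ms else
    c(left = unname(center_ms), right = unname(center_ms))
  res <- purrr::imap(list(left = groups$left, right = groups$right),
                     function(chs, side) {
    w <- channel_group_mean(avg, chs)
    list(auc = area_under_curve(w, centers[[side]], half_width_ms),
         lat = grand_peak_latency(w))
  })
  tibble(subject_id = subject_id,
         auc_left = res$left$auc, auc_right = res$right$auc,
         peak_latency_left = res$left$lat,
         peak_latency_right = res$right$lat)
}
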