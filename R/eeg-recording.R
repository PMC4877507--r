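# Multi-channel EEG container and its plain-text serialization.

#' Construct an EEG recording
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param rate_hz Sampling rate in Hz.
#' @param channel_labels Character vector, one label per channel.
#' @param events Tibble/data frame with columns `sample` (1-based index) and
#'   `code` (character), marking trial starts and tone onsets.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate_hz, channel_labels = NULL,
                          events = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a numeric channels x samples matrix.")
  }
  assert_scalar_num(rate_hz, "rate_hz", lower = 0, allow_zero = FALSE)
  channel_labels <- channel_labels %||% rownames(data) %||%
    paste0("E", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data)) {
    abort("`channel_labels` length must match the number of channels.")
  }
  events <- if (is.null(events)) {
    tibble(sample = integer(0), code = character(0))
  } else {
    ev <- as_tibble(events)
    if (!all(c("sample", "code") %in% names(ev))) {
      abort("`events` needs columns `sample` and `code`.")
    }
    if (nrow(ev) > 0 &&
        (min(ev$sample) < 1 || max(ev$sample) > ncol(data))) {
      abort("Event sample indices fall outside the recording.")
    }
    tibble(sample = as.integer(ev$sample), code = as.character(ev$code))
  }
  rownames(data) <- channel_labels
  structure(list(data = data, rate_hz = rate_hz,
                 channel_labels = channel_labels, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.4g s), %d events\n",
              nrow(x$data), ncol(x$data), x$rate_hz,
              ncol(x$data) / x$rate_hz, nrow(x$events)))
  invisible(x)
}

n_samples <- function(recording) ncol(recording$data)
n_channels <- function(recording) nrow(recording$data)

#' Write / read an EEG recording as CSV plus JSON sidecar
#'
#' The sample matrix is written as a samples x channels CSV with the channel
#' labels as header; sampling rate, event table and sample count go into a
#' JSON sidecar at `<path>.json`. The round trip is exact (full-precision
#' decimal serialization).
#'
#' @param recording An [eeg_recording()].
#' @param path CSV file path (the sidecar adds `.json`).
#' @return `write_eeg_csv()` returns `path` invisibly; `read_eeg_csv()` an
#'   [eeg_recording()].
#' @export
write_eeg_csv <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  df <- as.data.frame(t(recording$data))
  names(df) <- recording$channel_labels
  readr::write_csv(df, path)
  meta <- list(rate_hz = recording$rate_hz,
               n_samples = n_samples(recording),
               channel_labels = recording$channel_labels,
               events = list(sample = recording$events$sample,
                             code = recording$events$code))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_eeg_csv
#' @export
read_eeg_csv <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar)) {
    abort(sprintf("Recording files not found at '%s' (+ .json).", path))
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) != meta$n_samples ||
      !identical(names(df), as.character(meta$channel_labels))) {
    abort(sprintf(
      "File '%s' is truncated or inconsistent with its sidecar (%d rows, %d expected).",
      path, nrow(df), meta$n_samples))
  }
  events <- tibble(sample = as.integer(meta$events$sample %||% integer(0)),
                   code = as.character(meta$events$code %||% character(0)))
  eeg_recording(t(as.matrix(df)), meta$rate_hz,
                as.character(meta$channel_labels), events)
}

# Simulated montage geometry: channels are laid out in `n_rows` rows from
# front to back, each row split into a left and a right half. Labels are
# e.g. "F3L" = frontal row, position 3, left hemisphere.
montage_labels <- function(n_channels, n_rows = 4) {
  row_letter <- c("F", "C", "P", "O", "X", "Y")[seq_len(n_rows)]
  per_row <- ceiling(n_channels / n_rows)
  labs <- character(n_channels)
  for (i in seq_len(n_channels)) {
    r <- ((i - 1) %/% per_row) + 1
    k <- ((i - 1) %% per_row) + 1
    hemi <- if (k <= per_row / 2) "L" else "R"
    pos <- if (hemi == "L") k else k - floor(per_row / 2)
    labs[i] <- paste0(row_letter[r], pos, hemi)
  }
  labs
}

# Normalized front-to-back depth (0 = frontal-most row centre, 1 = back).
montage_depth <- function(n_channels, n_rows = 4) {
  per_row <- ceiling(n_channels / n_rows)
  row <- ((seq_len(n_channels) - 1) %/% per_row) + 1
  (row - 0.5) / n_rows
}

#' Default frontal channel groups of a simulated montage
#'
#' The frontal-most row of the montage split by hemisphere, mirroring the
#' eight-left / eight-right frontal electrode groups used for infant auditory
#' ERPs (the group size scales with the montage: 4 + 4 at 32 channels,
#' 8 + 8 at 64).
#'
#' @param channel_labels Labels as produced by the cohort simulator.
#' @return List with `left` and `right` character vectors.
#' @export
frontal_groups <- function(channel_labels) {
  frontal <- grep("^F", channel_labels, value = TRUE)
  list(left = grep("L$", frontal, value = TRUE),
       right = grep("R$", frontal, value = TRUE))
}
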