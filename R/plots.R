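# ggplot2 visualizations for the main result types.

#' Plot an amplitude spectrum
#'
#' @param object An `amp_spectrum`.
#' @param max_hz Upper frequency limit of the plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.amp_spectrum <- function(object, max_hz = 5, ...) {
  df <- dplyr::filter(as_tibble(object), .data$frequency_hz <= max_hz)
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency_hz, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(
      x = "Frequency (Hz)",
      y = if (is_noise_corrected(object)) {
        "Noise-subtracted amplitude (µV)"
      } else {
        "Amplitude"
      }) +
    ggplot2::theme_minimal()
}

#' Plot an averaged waveform
#'
#' @param object An `averaged_waveform`.
#' @param channels Optional subset of channel labels.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.averaged_waveform <- function(object, channels = NULL, ...) {
  channels <- channels %||% object$channel_labels
  idx <- match(channels, object$channel_labels)
  df <- purrr::map_dfr(idx, function(i) {
    tibble(channel = object$channel_labels[i],
           time_ms = waveform_times_ms(object),
           amplitude_uv = object$data[i, ])
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$amplitude_uv,
                                   colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3, show.legend = length(idx) <= 8) +
    ggplot2::labs(x = "Time (ms)", y = "Amplitude (µV)") +
    ggplot2::theme_minimal()
}

#' Group comparison of SS-EP amplitudes across tagged frequencies
#'
#' Mean +/- standard error of the noise-subtracted, channel-averaged SS-EP
#' amplitude per tagged frequency and group.
#'
#' @param cohort_table Cohort table with `ssep_<freq>` columns.
#' @param between Grouping column (`"music_classes"` or `"parent_trained"`).
#' @return A ggplot object.
#' @export
plot_cohort_amplitudes <- function(cohort_table,
                                   between = "music_classes") {
  amp_cols <- ssep_columns(cohort_table)
  df <- cohort_table |>
    tidyr::pivot_longer(all_of(amp_cols), names_to = "frequency",
                        values_to = "amplitude") |>
    mutate(frequency_hz = as.numeric(sub("^ssep_", "", .data$frequency)),
           group = factor(.data[[between]])) |>
    group_by(.data$frequency_hz, .data$group) |>
    summarise(mean = mean(.data$amplitude),
              se = sd(.data$amplitude) / sqrt(dplyr::n()),
              .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$frequency_hz), .data$mean,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(0.8), width = 0.2) +
    ggplot2::labs(x = "Frequency (Hz)",
                  y = "SS-EP amplitude (µV)", fill = between) +
    ggplot2::theme_minimal()
}
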