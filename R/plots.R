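#' Plot a spectral track
#'
#' Spectrogram heat map (dB scale) with the tracked heart-rate line overlaid,
#' the visual-inspection artifact used to judge signal quality by eye:
#' a clean record shows one narrow line; contact-loss artifacts show as
#' broadband vertical streaks.
#'
#' @param object A `spectral_track`.
#' @param max_bpm Upper frequency limit of the display, BPM.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spectral_track <- function(object, max_bpm = 240, ...) {
  keep <- object$freq * 60 <= max_bpm
  df <- tidyr::expand_grid(
    time_s = object$frames$time_s,
    bpm = object$freq[keep] * 60
  )
  df$db <- 10 * log10(pmax(as.vector(object$power[keep, ]), 1e-12))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$bpm)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$db)) +
    ggplot2::scale_fill_viridis_c(name = "power (dB)") +
    ggplot2::labs(x = "time (s)", y = "frequency (BPM)")
  if (!anyNA(object$frames$peak_hr)) {
    p <- p + ggplot2::geom_line(
      data = object$frames,
      ggplot2::aes(x = .data$time_s, y = .data$peak_hr),
      color = "yellow", linewidth = 0.4
    )
  }
  p
}

#' @export
plot.spectral_track <- function(x, ...) print(autoplot(x, ...))

#' Plot the heart-rate series of a processed record
#'
#' Time-domain and frequency-domain HR at the beat time stamps, plus the
#' reference when present; outlier beats are marked.
#'
#' @param object A `roma_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roma_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$hr, cols = dplyr::starts_with("hr_"),
                            names_to = "source", values_to = "hr",
                            names_prefix = "hr_")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$hr,
                                   color = .data$source)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_point(data = dplyr::filter(df, .data$outlier),
                        shape = 4, color = "red") +
    ggplot2::labs(x = "time (s)", y = "heart rate (BPM)",
                  title = object$record_id)
}

#' @export
plot.roma_result <- function(x, ...) print(autoplot(x, ...))

#' @importFrom rlang .data
NULL
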