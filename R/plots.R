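#' Plot a spike train with its Gamma signature
#'
#' @param object An `mms_result`.
#' @param ... Unused.
#' @return A ggplot: spike amplitudes over time with the fitted Gamma mean.
#' @export
autoplot.mms_result <- function(object, ...) {
  ggplot2::ggplot(object$spikes, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$time, yend = 0), linewidth = 0.3) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = object$gamma$mean, linetype = 2, colour = "red") +
    ggplot2::labs(
      x = "time (s)", y = "spike amplitude",
      title = sprintf(
        "micro-movement spikes: shape %.3g, NSR %.3g",
        object$gamma$shape, object$gamma$nsr
      )
    ) +
    ggplot2::theme_minimal()
}

#' Gamma parameter plane of a signature collection
#'
#' Log-log scatter of shape against scale (NSR) with confidence-interval
#' bars; the axis along which the shape-scale power law expresses itself.
#'
#' @param signatures List of `gamma_signature`s or a tibble with columns
#'   `shape`, `scale` (optionally CI columns and a `label`).
#' @return A ggplot.
#' @export
plot_gamma_plane <- function(signatures) {
  df <- if (is.data.frame(signatures)) {
    signatures
  } else {
    purrr::map_dfr(signatures, function(s) {
      tibble::tibble(
        shape = s$shape, scale = s$scale,
        shape_lo = s$shape_ci[1], shape_hi = s$shape_ci[2],
        scale_lo = s$scale_ci[1], scale_hi = s$scale_ci[2]
      )
    })
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$scale, y = .data$shape)) +
    ggplot2::geom_point()
  if (all(c("shape_lo", "scale_lo") %in% names(df))) {
    p <- p +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$shape_lo, ymax = .data$shape_hi), width = 0) +
      ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$scale_lo, xmax = .data$scale_hi), height = 0)
  }
  p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Gamma scale (NSR)", y = "Gamma shape") +
    ggplot2::theme_minimal()
}

#' Poincare plot of an IBI series
#'
#' Lag-1 scatter of each interval against its predecessor with the SD1/SD2
#' descriptors in the subtitle.
#'
#' @param ibi An [ibi_series()].
#' @return A ggplot.
#' @export
plot_poincare <- function(ibi) {
  rr <- valid_rr(ibi)
  df <- tibble::tibble(rr_n = rr[-length(rr)], rr_n1 = rr[-1])
  pc <- poincare(ibi)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rr_n, y = .data$rr_n1)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = expression(RR[n] ~ "(s)"), y = expression(RR[n + 1] ~ "(s)"),
      subtitle = sprintf("SD1 %.3g s, SD2 %.3g s", pc$sd1, pc$sd2)
    ) +
    ggplot2::theme_minimal()
}

#' Heat map of an IBI Morse-wavelet scalogram
#'
#' @param object An `ibi_scalogram` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ibi_scalogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$frequency, fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)", fill = "|CWT|") +
    ggplot2::theme_minimal()
}

#' EMD trajectory curves per emotion
#'
#' @param trajectory Output of [emd_trajectory()].
#' @return A ggplot of the per-region EMD-versus-reference curves.
#' @export
plot_emd_trajectory <- function(trajectory) {
  ggplot2::ggplot(
    trajectory,
    ggplot2::aes(
      x = .data$window_start, y = .data$emd,
      colour = .data$emotion, linetype = .data$region
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "window start (frame)", y = "EMD to reference") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.attack_decay_segments <- function(object, ...) {
  segs <- object$segments
  ggplot2::ggplot(segs, ggplot2::aes(
    x = .data$start_time, xend = .data$end_time,
    y = .data$phase, yend = .data$phase, colour = .data$phase
  )) +
    ggplot2::geom_segment(linewidth = 2) +
    ggplot2::scale_colour_manual(values = c(attack = "magenta", decay = "cyan")) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
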