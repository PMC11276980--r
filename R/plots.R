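#' Diagnostic plots
#'
#' ggplot2 figures for the main result types: detected events over the
#' preprocessed trace, the cumulative event-count curve, the inter-event
#' interval distribution with its modes, the wavelet spectrogram and the
#' f-I curve.
#'
#' @param sig preprocessed [timeseries()].
#' @param events an [event_train()].
#' @param threshold optional threshold to draw.
#' @return a ggplot object.
#' @export
plot_detection <- function(sig, events, threshold = NULL) {
  p <- ggplot2::ggplot(sig, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::geom_vline(
      xintercept = events$onset_s, colour = "firebrick", alpha = 0.5,
      linewidth = 0.2
    ) +
    ggplot2::labs(
      x = "time (s)", y = paste0("amplitude (", ts_units(sig), ")"),
      title = sprintf("%d detected events", nrow(events))
    )
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(
      yintercept = c(-threshold, threshold), linetype = "dashed"
    )
  }
  p
}

#' @rdname plot_detection
#' @param curve output of [cumulative_curve()].
#' @param discharges optional discharge table to shade.
#' @export
plot_cumulative <- function(curve, discharges = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$time_s, y = .data$count)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (s)", y = "cumulative uEE count")
  if (!is.null(discharges) && nrow(discharges)) {
    p <- p + ggplot2::geom_rect(
      data = discharges,
      ggplot2::aes(
        xmin = .data$start_s, xmax = .data$end_s, ymin = -Inf, ymax = Inf
      ),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.15
    )
  }
  p
}

#' @rdname plot_detection
#' @param object an `iei_summary`, `eps_cwt` or `firing_pattern` object.
#' @param ... unused.
#' @method autoplot iei_summary
#' @export
autoplot.iei_summary <- function(object, ...) {
  ggplot2::ggplot(
    object$density, ggplot2::aes(x = .data$interval_s, y = .data$density)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      xintercept = object$modes, linetype = "dashed", colour = "firebrick"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "inter-event interval (s)", y = "density (log scale)")
}

#' @rdname plot_detection
#' @method autoplot eps_cwt
#' @export
autoplot.eps_cwt <- function(object, ...) {
  df <- tidyr::expand_grid(
    freq_hz = object$freqs, time_s = object$time_s
  )
  df$power <- as.vector(t(object$power))
  ggplot2::ggplot(
    df, ggplot2::aes(x = .data$time_s, y = .data$freq_hz, fill = .data$power)
  ) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)", fill = "power")
}

#' @rdname plot_detection
#' @method autoplot firing_pattern
#' @export
autoplot.firing_pattern <- function(object, ...) {
  ggplot2::ggplot(
    object$fi_curve, ggplot2::aes(x = .data$current_pa, y = .data$rate_hz)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(
      xintercept = object$rheobase, linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::labs(x = "injected current (pA)", y = "firing rate (Hz)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
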