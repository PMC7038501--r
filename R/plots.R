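#' Plot the muscular-cortical feature plane
#'
#' Scatter of monitored contractions in the (muscular score, SMA-alpha
#' slope) plane with the operating thresholds as reference lines. The
#' loss-of-balance region is the top-left rectangle: score below the
#' muscular threshold and slope above the cortical one.
#'
#' @param detection a `lob_detection`.
#' @return A ggplot object.
#' @export
plot_feature_plane <- function(detection) {
  fp <- feature_plane(detection)
  fp <- fp[fp$phase == "monitoring", , drop = FALSE]
  p <- ggplot2::ggplot(fp, ggplot2::aes(x = .data$score,
                                        y = .data$m_SMA_alpha,
                                        colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "muscular score", y = "SMA alpha-band slope (dB/ms)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (is.finite(attr(fp, "ms_thr") %||% NA)) {
    p <- p + ggplot2::geom_vline(xintercept = attr(fp, "ms_thr"),
                                 linetype = "dashed")
  }
  if (is.finite(attr(fp, "cort_thr_sma_alpha") %||% NA)) {
    p <- p + ggplot2::geom_hline(yintercept = attr(fp, "cort_thr_sma_alpha"),
                                 linetype = "dashed")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.lob_detection <- function(object, ...) plot_feature_plane(object)

#' Plot the muscular score trace with its adaptive threshold
#'
#' @param detection a `lob_detection`.
#' @return A ggplot object.
#' @export
plot_score_trace <- function(detection) {
  f <- detection$features
  ggplot2::ggplot(f, ggplot2::aes(x = .data$time_s, y = .data$score)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$phase)) +
    ggplot2::geom_hline(yintercept = detection$thresholds$ms_thr,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "time (s)", y = "muscular score", colour = NULL) +
    ggplot2::theme_minimal()
}
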