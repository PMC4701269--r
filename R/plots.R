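#' Plot a pitch track
#'
#' F0 over time (points, voiced frames only) above the pitch-strength trace,
#' optionally shading detected voiced segments.
#'
#' @param object A `pitch_track`.
#' @param segments Optional segment tibble to shade.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot pitch_track
#' @export
autoplot.pitch_track <- function(object, segments = NULL, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("f0", "strength"), names_to = "panel") |>
    dplyr::mutate(panel = factor(.data$panel,
      levels = c("f0", "strength"),
      labels = c("F0 (Hz)", "pitch strength")
    ))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value))
  if (!is.null(segments) && nrow(segments) > 0) {
    p <- p + ggplot2::geom_rect(
      data = segments,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "steelblue", alpha = 0.15
    )
  }
  p +
    ggplot2::geom_point(size = 0.4, na.rm = TRUE) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a specificity/sensitivity threshold curve
#'
#' @param object A `threshold_curve` from [sweep_threshold()].
#' @param min_spec,min_sens Optional criterion lines to draw.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot threshold_curve
#' @export
autoplot.threshold_curve <- function(object, min_spec = 0.9, min_sens = 0.6, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("sensitivity", "specificity"), names_to = "measure")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$threshold, y = .data$value, colour = .data$measure
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(min_sens, min_spec), linetype = "dashed", alpha = 0.4) +
    ggplot2::labs(x = "pitch-strength threshold", y = NULL, colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot per-segment features across a recording
#'
#' @param object A feature tibble from [segment_features()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot segment_feature_tbl
#' @export
autoplot.segment_feature_tbl <- function(object, ...) {
  plot_segment_features(object)
}

#' @rdname autoplot.segment_feature_tbl
#' @param features A feature tibble from [segment_features()].
#' @export
plot_segment_features <- function(features) {
  df <- features |>
    tidyr::pivot_longer(c("mean_f0", "std_f0", "jitter"), names_to = "feature") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$start + .data$end) / 2, y = .data$value
  )) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~ .data$feature, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "segment midpoint (s)", y = NULL) +
    ggplot2::theme_minimal()
}
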