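#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Adult-size distribution of an event log
#'
#' @param events An event tibble from [simulate_filaments()] or
#'   [simulate_batch()].
#' @param target_size Optional target adult size to mark with a dashed
#'   line.
#' @return A ggplot.
#' @export
plot_adult_sizes <- function(events, target_size = NULL) {
  p <- ggplot2::ggplot(events, ggplot2::aes(x = .data$parent_size)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "adult size (cells)", y = "fragmentation events")
  if (!is.null(target_size))
    p <- p + ggplot2::geom_vline(xintercept = target_size,
                                 linetype = "dashed")
  p
}

#' Reproduction-mode frequencies of an event log
#'
#' @inheritParams plot_adult_sizes
#' @return A ggplot bar chart over the five modes.
#' @export
plot_mode_frequencies <- function(events) {
  freqs <- mode_frequencies(events)
  ggplot2::ggplot(freqs,
                  ggplot2::aes(x = .data$mode, y = .data$frequency)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "frequency") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @rdname plot_adult_sizes
#' @param object A `"filament_sim"`.
#' @param ... Unused.
#' @export
autoplot.filament_sim <- function(object, target_size = NULL, ...) {
  plot_adult_sizes(object$events, target_size = target_size)
}

#' Heat map of a threshold scan
#'
#' @param object A `"filament_scan"` from [grid_scan()].
#' @param metric `"deviation"` (signed mean-size deviation) or `"l2"`.
#' @param ... Unused.
#' @return A ggplot tile map over the threshold grid.
#' @export
autoplot.filament_scan <- function(object, metric = c("deviation", "l2"),
                                   ...) {
  metric <- match.arg(metric)
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$theta1, y = .data$theta2,
                                    fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "theta1", y = "theta2",
                  title = paste(attr(object, "logic"), "combination"))
  if (metric == "deviation")
    p <- p + ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                           high = "red", midpoint = 0)
  p
}

#' Calibration objective across candidate thresholds
#'
#' @param object A `"filament_calibration"` from [calibrate_threshold()].
#' @param ... Unused.
#' @return A ggplot of mean squared error against threshold, with the
#'   chosen optimum marked.
#' @export
autoplot.filament_calibration <- function(object, ...) {
  grid <- object$grid[is.finite(object$grid$mse), ]
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$theta, y = .data$mse,
                                     colour = .data$pass)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$theta, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "threshold", y = "mean squared error vs target")
}
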