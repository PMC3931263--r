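# ggplot2 displays for traces, criterion traces, fits and reduced
# segment lists.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a sweep trace
#'
#' @param object A [trace()].
#' @param reduce_px If non-`NULL`, apply min-max reduction to this many
#'   pixel columns before drawing (see [reduce_trace()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sweep_trace
#' @export
autoplot.sweep_trace <- function(object, reduce_px = NULL, ...) {
  if (!is.null(reduce_px)) {
    seg <- reduce_trace(object, reduce_px)
    return(plot_segments(seg) +
             ggplot2::labs(x = "time (ms)", y = object$y_unit))
  }
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = object$y_unit) +
    ggplot2::theme_minimal()
}

#' Plot a detection-criterion trace with its threshold
#'
#' @param object A `criterion_trace`.
#' @param threshold_sd Optional threshold (criterion-SD multiples) drawn as
#'   a dashed line.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot criterion_trace
#' @export
autoplot.criterion_trace <- function(object, threshold_sd = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$time, y = .data$criterion)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "steelblue") +
    ggplot2::labs(x = "time (ms)", y = paste(object$method, "criterion")) +
    ggplot2::theme_minimal()
  if (!is.null(threshold_sd)) {
    p <- p + ggplot2::geom_hline(
      yintercept = object$center + threshold_sd * object$noise_sd,
      linetype = "dashed", colour = "red")
  }
  p
}

#' Plot a fit over its data
#'
#' @param object A `sweep_fit` from [fit_model()].
#' @param ... Unused.
#' @return A ggplot showing the fitted region and the model curve.
#' @method autoplot sweep_fit
#' @export
autoplot.sweep_fit <- function(object, ...) {
  df <- tibble::tibble(time = object$times, observed = object$observed,
                       fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed), linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "time (ms)", y = NULL,
                  title = sprintf("%s fit (normalized SSE %.2g)",
                                  object$model$name, object$sse)) +
    ggplot2::theme_minimal()
}

#' Draw a reduced segment list
#'
#' @param segments Tibble from [reduce_trace()].
#' @return A ggplot built from `geom_segment`, one drawing primitive per
#'   row — exactly what a rasterizing backend would receive.
#' @export
plot_segments <- function(segments) {
  ggplot2::ggplot(segments,
                  ggplot2::aes(x = .data$x1, y = .data$y1,
                               xend = .data$x2, yend = .data$y2)) +
    ggplot2::geom_segment(linewidth = 0.3) +
    ggplot2::theme_minimal()
}
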