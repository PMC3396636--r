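#' Plot a decay fit
#'
#' Normalized quantities against chase time with the fitted exponential
#' (and plateau, when fitted) overlaid; y on a log scale by default, where a
#' single exponential is a straight line.
#'
#' @param object A [fit_decay()] result.
#' @param log_y Use a log10 y axis (default `TRUE`).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.decay_fit <- function(object, log_y = TRUE, ...) {
  grid <- tibble::tibble(
    chase_time = seq(min(object$data$chase_time),
                     max(object$data$chase_time), length.out = 200))
  grid$quantity <- .predict_decay(object, grid$chase_time)
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(.data$chase_time, .data$quantity)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("chase time (%s)", object$unit),
      y = "relative quantity",
      title = sprintf("Exponential decay fit: k = %.4g per %s", object$k,
                      object$unit),
      subtitle = sprintf("%s fit, R-squared = %.3f (%s scale)%s",
                         object$method, object$r_squared, object$scale_of_r2,
                         if (is.finite(object$plateau))
                           sprintf(", plateau = %.3g", object$plateau)
                         else "")
    )
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a growth fit
#'
#' Cell counts on a log axis with the fitted exponential expansion line.
#'
#' @param object A [fit_expansion()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.growth_fit <- function(object, ...) {
  grid <- tibble::tibble(
    time = seq(min(object$data$time), max(object$data$time),
               length.out = 100))
  grid$count <- object$c0 * exp(object$j * grid$time)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time, .data$count)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = sprintf("time (%s)", object$unit), y = "cells",
      title = sprintf("Culture expansion: j = %.4g per %s", object$j,
                      object$unit),
      subtitle = sprintf("doubling time %.3g %s, R-squared = %.3f",
                         object$doubling_time, object$unit, object$r_squared)
    )
}

#' Plot a Monte-Carlo design comparison
#'
#' Distribution of half-life estimates per design from [compare_designs()],
#' with the shared truth marked.
#'
#' @param object A [compare_designs()] summary (carrying its `"runs"`
#'   attribute).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.design_comparison <- function(object, ...) {
  plot_design_comparison(object)
}

#' @rdname autoplot.design_comparison
#' @param comparison A [compare_designs()] result.
#' @export
plot_design_comparison <- function(comparison, ...) {
  runs <- attr(comparison, "runs")
  if (is.null(runs)) stop("comparison lacks per-simulation runs",
                          call. = FALSE)
  truth <- comparison$true_t_half[1]
  ggplot2::ggplot(dplyr::filter(runs, !is.na(.data$t_half)),
                  ggplot2::aes(.data$design, .data$t_half)) +
    ggplot2::geom_violin(fill = "grey90") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.3, size = 0.6) +
    ggplot2::geom_hline(yintercept = truth, linetype = 2) +
    ggplot2::labs(
      x = NULL, y = sprintf("estimated half-life (%s)", comparison$unit[1]),
      title = "Half-life estimates by chase design",
      subtitle = sprintf("dashed line: true half-life (%.4g %s)", truth,
                         comparison$unit[1])
    )
}
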