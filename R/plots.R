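# ggplot2 figures for the three standard CEA displays: tornado diagram,
# acceptability curves, cost-effectiveness plane with confidence ellipse.

#' Tornado diagram
#'
#' Horizontal bars spanning each parameter's output range, widest on top,
#' with a vertical line at the base-case output.
#'
#' @param result A [tornado()] result.
#' @param base_output Base-case output value for the reference line
#'   (optional).
#' @return A ggplot object.
#' @export
plot_tornado <- function(result, base_output = NULL) {
  stopifnot(inherits(result, "tornado_result"))
  df <- tibble::tibble(
    parameter = factor(result$parameter, levels = rev(result$parameter)),
    lo = pmin(result$output_low, result$output_high),
    hi = pmax(result$output_low, result$output_high)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(y = parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = lo, xend = hi,
                                       yend = parameter),
                          linewidth = 5, colour = "steelblue") +
    ggplot2::labs(x = "model output", y = NULL, title = "Tornado diagram") +
    ggplot2::theme_minimal()
  if (!is.null(base_output)) {
    p <- p + ggplot2::geom_vline(xintercept = base_output, linetype = "dashed")
  }
  p
}

#' Cost-effectiveness acceptability curves
#'
#' @param curve A [ceac()] result.
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve) {
  stopifnot(inherits(curve, "ceac_curve"))
  ggplot2::ggplot(curve, ggplot2::aes(x = wtp, y = probability,
                                      colour = strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "willingness-to-pay (US$/QALY)",
                  y = "probability cost-effective",
                  title = "Cost-effectiveness acceptability curves") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness plane
#'
#' Scatter of incremental (effect, cost) pairs per PSA draw with the
#' fitted confidence ellipse and a WTP ray through the origin.
#'
#' @param plane A [ce_plane()] result.
#' @param wtp Optional willingness-to-pay to draw as a line through the
#'   origin.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(plane, wtp = NULL) {
  p <- ggplot2::ggplot(plane$cloud,
                       ggplot2::aes(x = delta_effect,
                                    y = delta_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::labs(x = "incremental effect (QALY)",
                  y = "incremental cost (US$)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
  if (!is.null(plane$ellipse)) {
    p <- p + ggplot2::geom_path(data = ellipse_points(plane$ellipse),
                                colour = "firebrick")
  }
  if (!is.null(wtp)) {
    p <- p + ggplot2::geom_abline(slope = wtp, intercept = 0,
                                  linetype = "dashed")
  }
  p
}

utils::globalVariables(c("parameter", "lo", "hi", "wtp", "probability",
                         "strategy", "delta_effect", "delta_cost"))
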