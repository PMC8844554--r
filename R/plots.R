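## ggplot2 displays: cost-effectiveness plane and acceptability curve.

#' Cost-effectiveness plane
#'
#' Scatter of the lifetime incremental (QALY, cost) replicates, with the
#' point estimate and, optionally, the willingness-to-pay ray.
#'
#' @param replicates A `replicate_table` (or `cea_result`).
#' @param threshold Optional willingness-to-pay per QALY to draw as a ray.
#' @param point Optional point estimate tibble with `dqaly`, `dcost`.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(replicates, threshold = NULL, point = NULL) {
  if (inherits(replicates, "cea_result")) {
    point <- point %||% tibble::tibble(dqaly = replicates$point$dqaly,
                                       dcost = replicates$point$dcost)
    replicates <- replicates$replicates
  }
  p <- ggplot2::ggplot(replicates,
                       ggplot2::aes(x = .data$lifetime_dqaly,
                                    y = .data$lifetime_dcost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_abline(slope = threshold, intercept = 0,
                                  linetype = "dashed", colour = "grey40")
  }
  if (!is.null(point)) {
    p <- p + ggplot2::geom_point(data = point,
                                 ggplot2::aes(x = .data$dqaly,
                                              y = .data$dcost),
                                 colour = "red", size = 2)
  }
  p
}

#' Cost-effectiveness acceptability curve
#'
#' @param ceac_table Output of [ceac()] (or a `cea_result`).
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_table) {
  if (inherits(ceac_table, "cea_result")) ceac_table <- ceac_table$ceac
  ggplot2::ggplot(ceac_table, ggplot2::aes(x = .data$threshold,
                                           y = .data$probability)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay per QALY",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Autoplot a fitted analysis
#'
#' @param object A `cea_result`.
#' @param type `"ce_plane"` or `"ceac"`.
#' @param ... Passed to the underlying plot function.
#' @return A ggplot object.
#' @export
autoplot.cea_result <- function(object, type = c("ce_plane", "ceac"), ...) {
  type <- match.arg(type)
  if (type == "ce_plane") plot_ce_plane(object, ...) else plot_ceac(object)
}
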