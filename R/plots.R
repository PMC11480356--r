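#' Density plot of per-stock slopes, with and without AR1
#'
#' The general-tendency view of the analysis: kernel densities of the
#' estimated per-stock density slopes, one panel per response, coloured by
#' model variant. A mode below zero indicates a compensatory tendency.
#'
#' @param slopes Tibble with `response`, `model`, `slope` columns.
#' @return A ggplot object.
#' @export
plot_slope_density <- function(slopes) {
  ggplot2::ggplot(slopes, ggplot2::aes(x = .data$slope,
                                       colour = .data$model,
                                       fill = .data$model)) +
    ggplot2::geom_density(alpha = 0.25) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::facet_wrap(~response, scales = "free") +
    ggplot2::labs(x = "per-stock density slope", y = "density",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Per-stock slope estimates by taxonomic group
#'
#' Dot plot of per-stock slopes by group, highlighting significant stocks.
#'
#' @param slopes Tibble with `stock`, `order`, `response`, `model`, `slope`,
#'   `p` columns (e.g. `group_summaries()$slopes`).
#' @param alpha Significance threshold for highlighting.
#' @return A ggplot object.
#' @export
plot_stock_slopes <- function(slopes, alpha = 0.05) {
  d <- dplyr::mutate(slopes, significant = .data$p < alpha)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$order, y = .data$slope,
                                  colour = .data$significant)) +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::facet_grid(model ~ response, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "density slope",
                  colour = paste0("p < ", alpha)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @export
#' @importFrom ggplot2 autoplot
autoplot.dd_lmm <- function(object, ...) {
  if (is.null(object$per_stock))
    stop("autoplot.dd_lmm needs a fit with per-stock slopes")
  d <- dplyr::mutate(object$per_stock,
                     lo = .data$slope - 1.96 * .data$se,
                     hi = .data$slope + 1.96 * .data$se,
                     significant = .data$p < 0.05)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$stock,
                                                     .data$slope),
                                  y = .data$slope,
                                  colour = .data$significant)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo,
                                          ymax = .data$hi)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "per-stock density slope",
                  colour = "p < 0.05") +
    ggplot2::theme_minimal()
}
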