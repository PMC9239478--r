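# ggplot2 displays for fitted waveforms, effect surfaces and interaction
# plots.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted pulse waveform over the observed series
#'
#' @param object A `harmonic_fit` object.
#' @param n_grid Number of evaluation points for the fitted curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.harmonic_fit <- function(object, n_grid = 400L, ...) {
  obs <- tibble::tibble(t = object$t, intensity = object$intensity)
  tg <- seq(min(object$t), max(object$t), length.out = n_grid)
  fitl <- tibble::tibble(t = tg,
                         intensity = reconstruct_waveform(object, tg))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$t, y = .data$intensity)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(data = fitl, colour = "#b2182b") +
    ggplot2::labs(
      x = "time (cardiac-cycle fractions)",
      y = "green-channel intensity",
      title = sprintf("Harmonic regression fit (order %d, HRWa = %.3g)",
                      object$order, object$hrwa)
    ) +
    ggplot2::theme_minimal()
}

#' Trellis plot of a fixed-effect prediction grid
#'
#' Distance along the vessel on the x axis, faceted by ICP (columns) and
#' induced IOP (rows), with Wald standard-error bands where available.
#'
#' @param grid Tibble from [effect_grid()].
#' @param response_label Y-axis label.
#' @return A ggplot object.
#' @export
plot_effect_grid <- function(grid, response_label = "transformed amplitude") {
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$v_dist_mm,
                                          y = .data$estimate))
  if (any(is.finite(grid$std_error))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$estimate - 1.96 * .data$std_error,
                   ymax = .data$estimate + 1.96 * .data$std_error),
      fill = "grey80"
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$iop_i_mmHg),
      cols = ggplot2::vars(.data$icp_cmH2O),
      labeller = ggplot2::label_both
    ) +
    ggplot2::labs(x = "distance along vessel (mm)", y = response_label) +
    ggplot2::theme_minimal()
}

#' Interaction plot of vessel-by-ICP cell means
#'
#' @param cells An [cell_means()] result.
#' @return A ggplot object.
#' @export
plot_interaction_cells <- function(cells) {
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$vessel, y = .data$mean,
                                      colour = .data$icp_group,
                                      group = .data$icp_group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::scale_colour_manual(values = c(normal = "black",
                                            high = "#1b7837")) +
    ggplot2::labs(x = NULL, y = attr(cells, "parameter") %||% "cell mean",
                  colour = "ICP group") +
    ggplot2::theme_minimal()
}
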