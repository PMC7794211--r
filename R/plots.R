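#' Partial regression leverage plots for a fitted framework model
#'
#' One panel per factor: partial residuals of the log biomass ratio
#' against partial residuals of the log factor, with the partial
#' regression line (whose slope equals the full-model coefficient) and
#' the partial correlation annotated.
#'
#' @param object An [fit_framework()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hp_fit <- function(object, ...) {
  panels <- purrr::map_dfr(c("a_nut", "a_edi", "mu", "theta"), function(pr) {
    pl <- partial_leverage(object, pr)
    dplyr::mutate(pl$residuals,
                  predictor = sprintf("%s (partial r = %.2f, p = %.3g)",
                                      pr, pl$partial_r, pl$p_value))
  })
  ggplot2::ggplot(panels, ggplot2::aes(.data$x_resid, .data$y_resid)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linetype = "dashed", colour = "black",
                         linewidth = 0.5) +
    ggplot2::facet_wrap(~predictor, scales = "free_x") +
    ggplot2::labs(x = "partial residual of log factor",
                  y = "partial residual of log(H/P)") +
    ggplot2::theme_minimal()
}

#' Plot a photosynthesis-irradiance curve with its data
#'
#' @param curve A [pi_curve()] (typically from [fit_pi_curve()]).
#' @param points Optional data frame of measured `par`, `rate` points.
#' @param par_max Upper irradiance for the curve (defaults to 1.2x the
#'   data range or a saturating span).
#' @return A ggplot object.
#' @export
plot_pi_curve <- function(curve, points = NULL, par_max = NULL) {
  stopifnot(inherits(curve, "hp_picurve"))
  if (is.null(par_max)) {
    par_max <- if (!is.null(points)) 1.2 * max(points$par)
               else 5 * curve$p_max / curve$alpha
  }
  grid <- tibble(par = seq(0, par_max, length.out = 200))
  grid$rate <- pi_response(curve, grid$par)
  p <- ggplot2::ggplot(grid, ggplot2::aes(.data$par, .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(PAR ~ (mu * mol ~ photon ~ m^-2 ~ s^-1)),
                  y = expression(gC ~ g ~ "chl-a"^-1 ~ h^-1)) +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(data = as_tibble(points))
  }
  p
}
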