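#' Plot threshold-attainment curves
#'
#' @param curves long-format curve table (`strategy`, `cohort`, `t`,
#'   `value`), e.g. the `curves` element of a [run_experiment()] bundle.
#' @param cohort cohort name to display.
#' @return a ggplot object.
#' @export
plot_attainment <- function(curves, cohort) {
  dat <- curves[curves$cohort == cohort, , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t, y = 100 * .data$value,
                                    colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "threshold t (minutes)",
                  y = "patients attaining (%)",
                  colour = "strategy",
                  title = sprintf("Threshold attainment, %s", cohort)) +
    ggplot2::theme_minimal()
}

#' Plot a utility scatter with contours
#'
#' Attainment pairs per strategy at a fixed threshold, coloured by utility,
#' over iso-utility contours of the chosen family. Axes are raw attainment
#' percentages.
#'
#' @param scatter a [utility_scatter()] result.
#' @param params the [utility_params()] used to build it.
#' @return a ggplot object.
#' @export
plot_utility_scatter <- function(scatter, params) {
  g <- expand.grid(v_low = seq(0, 1, by = 0.01), v_mid = seq(0, 1, by = 0.01))
  g$u <- utility_value(g$v_low, g$v_mid, params)
  ggplot2::ggplot() +
    ggplot2::geom_contour(data = g,
                          ggplot2::aes(x = 100 * .data$v_low, y = 100 * .data$v_mid,
                                       z = .data$u),
                          breaks = attr(scatter, "contour_levels") %||% seq(0.1, 0.9, 0.1),
                          colour = "grey70") +
    ggplot2::geom_point(data = scatter,
                        ggplot2::aes(x = 100 * .data$v_low, y = 100 * .data$v_mid,
                                     colour = .data$u), size = 3) +
    ggplot2::geom_text(data = scatter,
                       ggplot2::aes(x = 100 * .data$v_low, y = 100 * .data$v_mid,
                                    label = .data$strategy),
                       vjust = -1, size = 3) +
    ggplot2::scale_colour_gradient(low = "red", high = "forestgreen", limits = c(0, 1)) +
    ggplot2::labs(x = "low-acuity attainment (%)", y = "mid-acuity attainment (%)",
                  colour = "utility") +
    ggplot2::theme_minimal()
}
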