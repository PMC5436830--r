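#' Plot a minimal-distance distribution
#'
#' Renders the normalised histogram of a per-frame minimal-distance series
#' in the style of binding-site distance-distribution figures.
#'
#' @param series Tibble from [min_distance_series()] (or any tibble with a
#'   `min_dist` column).
#' @param bin_width Histogram bin width, Angstrom.
#' @return A ggplot object.
#' @export
plot_distance_histogram <- function(series, bin_width = 0.1) {
  h <- distance_histogram(series, bin_width)
  lab <- attr(series, "label") %||% "minimal distance"
  ggplot2::ggplot(h, ggplot2::aes(
    x = (.data$bin_lo + .data$bin_hi) / 2, y = .data$freq
  )) +
    ggplot2::geom_col(width = bin_width, fill = "steelblue") +
    ggplot2::labs(
      x = "minimal distance [Å]", y = "frequency", title = lab
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn mg_occupancy Bar chart of the coordination-state fractions.
#' @param object `mg_occupancy` tibble.
#' @param ... Ignored.
#' @export
autoplot.mg_occupancy <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$state, y = .data$fraction)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "occupancy fraction",
                  title = "Mg2+ coordination-state occupancy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @describeIn lambda_series Mean dH/dlambda profile over the lambda grid,
#'   with the trapezoidal integral in the subtitle.
#' @param object A `lambda_series`.
#' @param t_eq_ps Equilibration discard passed to [ti_integrate()].
#' @param ... Ignored.
#' @export
autoplot.lambda_series <- function(object, t_eq_ps = 0, ...) {
  est <- ti_integrate(object, t_eq_ps)
  df <- tibble(lambda = object$lambda, mean_dhdl = est$details$window_means)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda, y = .data$mean_dhdl)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = expression(lambda),
      y = sprintf("mean dH/dλ [%s]", object$unit),
      title = "Thermodynamic-integration profile",
      subtitle = sprintf("trapezoidal ΔG = %.4g %s",
                         est$delta_g, est$unit)
    ) +
    ggplot2::theme_minimal()
}
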