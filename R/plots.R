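#' Forest plot of city-specific calibration coefficients
#'
#' Point estimates with 95% intervals, one row per city, point size
#' proportional to the precision (inverse variance) of the coefficient.
#' Cities flagged as non-identifiable or undersized are omitted.
#'
#' @param city_fits A `calib_city_fits` tibble from [city_specific_fits()].
#' @param ref Reference line(s) to draw (default the no-attenuation value 1
#'   and 0).
#' @return A ggplot object.
#' @export
plot_city_forest <- function(city_fits, ref = c(0, 1)) {
  d <- filter(as_tibble(city_fits), !is.na(.data$gamma1))
  if (nrow(d) == 0) abort("No estimable city coefficients to plot.")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gamma1,
                                  y = stats::reorder(.data$city_id,
                                                     .data$gamma1))) +
    ggplot2::geom_vline(xintercept = ref, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2, colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight), shape = 15,
                        colour = "steelblue4", show.legend = FALSE) +
    ggplot2::scale_size_area(max_size = 6) +
    ggplot2::labs(x = "City-specific calibration coefficient",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.calib_city_fits <- function(object, ...) {
  plot_city_forest(object, ...)
}

#' @export
autoplot.calib_loocv <- function(object, ...) {
  d <- filter(object$per_city, !is.na(.data$observed),
              !is.na(.data$predicted))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(colour = "steelblue4") +
    ggplot2::geom_text(ggplot2::aes(label = .data$city_id), vjust = -0.7,
                       size = 3) +
    ggplot2::labs(
      x = "Observed city coefficient (per-city fit)",
      y = "Predicted from left-out covariate model",
      title = sprintf("LOOCV: r = %.2f, mean rel. bias = %.2f",
                      object$correlation, object$mean_relative_bias)) +
    ggplot2::theme_minimal()
}
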