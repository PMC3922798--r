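#' Tidy a calibration mixed-model fit
#'
#' @param x A `calib_fit`.
#' @param effects `"fixed"` for the fixed effects, `"ran_pars"` for the
#'   variance components.
#' @param conf.int,conf.level Add Wald confidence intervals to the fixed
#'   effects.
#' @param ... Unused.
#' @return A tibble in \pkg{broom} layout (`term`, `estimate`,
#'   `std.error`, `statistic`; variance components as `term`, `estimate`).
#' @export
tidy.calib_fit <- function(x, effects = c("fixed", "ran_pars"),
                           conf.int = FALSE, conf.level = 0.95, ...) {
  effects <- match.arg(effects)
  if (effects == "ran_pars") {
    return(tibble(
      term = c("var_city_intercept", "var_subject_intercept",
               "var_city_slope", "var_residual"),
      estimate = c(x$sigma2_city, x$sigma2_subject, x$sigma2_slope_city,
                   x$sigma2_w)))
  }
  se <- sqrt(diag(x$vcov_gamma))
  out <- tibble(term = names(x$gamma), estimate = unname(x$gamma),
                std.error = unname(se),
                statistic = unname(x$gamma / se))
  if (conf.int) {
    zq <- qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - zq * out$std.error
    out$conf.high <- out$estimate + zq * out$std.error
  }
  out
}

#' Glance at a calibration mixed-model fit
#'
#' @param x A `calib_fit`.
#' @param ... Unused.
#' @return A one-row tibble with sample sizes, variance components,
#'   log-likelihood, and convergence information.
#' @export
glance.calib_fit <- function(x, ...) {
  tibble(model = x$model, estimation = x$estimation,
         nobs = x$n_obs, n_subjects = x$n_subjects, n_cities = x$n_cities,
         sigma2_city = x$sigma2_city, sigma2_subject = x$sigma2_subject,
         sigma2_slope_city = x$sigma2_slope_city, sigma2_w = x$sigma2_w,
         logLik = if (x$estimation == "REML") x$loglik_reml else x$loglik_ml,
         converged = x$converged,
         n_boundary = length(x$boundary_flags))
}

#' @export
tidy.calib_loocv <- function(x, ...) {
  x$per_city
}

#' @export
glance.calib_loocv <- function(x, ...) {
  tibble(correlation = x$correlation,
         mean_relative_bias = x$mean_relative_bias,
         mean_absolute_bias = x$mean_absolute_bias,
         n_used = x$n_used, n_failed = x$n_failed)
}

#' @export
glance.calib_het <- function(x, ...) {
  tibble(lrt = x$lrt, p_value = x$p_value, boundary = x$boundary,
         sigma2_slope_city = x$sigma2_slope_city)
}

#' Serialize a fit or report to a flat JSON file
#'
#' Writes the numeric content of a `calib_fit` (fixed effects, variance
#' components, likelihoods, sizes, flags) as JSON.
#'
#' @param fit A `calib_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "calib_fit"))
  obj <- list(model = fit$model, true_exposure = fit$true_exposure,
              surrogate = fit$surrogate, estimation = fit$estimation,
              gamma = as.list(fit$gamma),
              vcov_gamma = unclass(fit$vcov_gamma),
              sigma2_city = fit$sigma2_city,
              sigma2_subject = fit$sigma2_subject,
              sigma2_slope_city = fit$sigma2_slope_city,
              sigma2_w = fit$sigma2_w,
              loglik_reml = fit$loglik_reml, loglik_ml = fit$loglik_ml,
              n_obs = fit$n_obs, n_subjects = fit$n_subjects,
              n_cities = fit$n_cities, converged = fit$converged,
              boundary_flags = fit$boundary_flags)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
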