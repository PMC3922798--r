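#' Configuration for the synthetic multi-city panel generator
#'
#' Bundles every ground-truth parameter of the generative model behind
#' [simulate_panel()]. Defaults describe a study of the size and exposure
#' scale typical of pooled U.S. personal-monitoring panels: nine cities,
#' monthly ambient PM2.5 around 16 ug/m3, personal/ambient sulfate ratios
#' around 0.64, and a calibration slope of 0.54.
#'
#' Two generation modes are supported. `"regression_truth"` draws the
#' surrogate exposure first and then the true exposure exactly from the
#' calibration mixed model, so fitted coefficients are directly comparable
#' to the configured truth. `"mechanistic"` instead simulates the exposure
#' physics (a city-month ambient field, per-subject infiltration ratios,
#' non-ambient indoor sources, monitor and prediction errors); the
#' attenuation of the fitted slope is then an emergent property.
#'
#' @param n_cities,subjects_per_city,months_per_subject Number of cities,
#'   subjects per city, and consecutive sampled months per subject.
#' @param days_per_month_sampled Personal sampling days per subject-month
#'   (drawn without replacement from days 1--28).
#' @param gamma0 Fixed intercept (ug/m3).
#' @param gamma1_true True calibration slope (unitless).
#' @param gamma2_true Fixed winter effect (ug/m3; winter coded 1).
#' @param gamma4_true Interaction of the surrogate with one raw-scale city
#'   covariate (per covariate unit); 0 disables it.
#' @param gamma4_covariate Name of the city covariate carrying `gamma4_true`.
#' @param sigma_city,sigma_subject,sigma_slope_city,sigma_w Standard
#'   deviations of the city random intercept, subject random intercept,
#'   city random slope, and residual (ug/m3; slope unitless).
#' @param ambient_mean,ambient_sd Mean and SD of the city-month ambient
#'   PM2.5 field (ug/m3).
#' @param ambient_daily_sd Day-to-day SD of ambient PM2.5 around its
#'   city-month level (ug/m3). This variation is shared by the monitor and,
#'   in mechanistic mode, by personal exposure of ambient origin, so it
#'   carries the temporal-mismatch structure probed by the matched-days
#'   sensitivity analysis. Default 0 keeps the monthly surrogate exact.
#' @param sulfate_ratio_mean,sulfate_ratio_sd Personal/ambient sulfate ratio
#'   distribution; drawn once per subject from a normal truncated to
#'   \[0, 1.5\].
#' @param nonambient_mean,nonambient_sd Indoor/personal-source PM2.5
#'   (ug/m3), mechanistic mode only.
#' @param monitor_error_sd Daily instrument/site error of the city monitor
#'   around the city-month ambient level (ug/m3).
#' @param model_pred_error_sd Error of the outdoor-home monthly prediction
#'   around the city-month ambient level (ug/m3).
#' @param mode `"regression_truth"` or `"mechanistic"` (see Details).
#' @param age_range Range of adult ages, drawn uniformly.
#' @param minor_fraction Fraction of subjects generated as minors
#'   (ages 10--17); 0 by default, available to exercise the adult-only
#'   eligibility filter.
#' @param residence_radius_mi Radius (miles) of the disc around the city
#'   centroid within which residences are scattered uniformly.
#' @param distant_monitor_city Optional city index whose monitor is placed
#'   about 45 miles from the centroid, to exercise the 30-mile
#'   monitor-matching rule.
#' @param seed Integer seed; identical seed and configuration give
#'   bit-identical datasets.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_panel()]
#' @export
#' @examples
#' cfg <- sim_config(n_cities = 3, subjects_per_city = 5, seed = 7)
#' cfg$gamma1_true
sim_config <- function(n_cities = 9,
                       subjects_per_city = 30,
                       months_per_subject = 6,
                       days_per_month_sampled = 7,
                       gamma0 = 5,
                       gamma1_true = 0.54,
                       gamma2_true = -2,
                       gamma4_true = 0,
                       gamma4_covariate = "vehicles_per_unit",
                       sigma_city = 1,
                       sigma_subject = 2,
                       sigma_slope_city = 0.15,
                       sigma_w = 3,
                       ambient_mean = 15.86,
                       ambient_sd = 5.58,
                       ambient_daily_sd = 0,
                       sulfate_ratio_mean = 0.64,
                       sulfate_ratio_sd = 0.25,
                       nonambient_mean = 14.8,
                       nonambient_sd = 8,
                       monitor_error_sd = 0,
                       model_pred_error_sd = 2,
                       mode = c("regression_truth", "mechanistic"),
                       age_range = c(40, 90),
                       minor_fraction = 0,
                       residence_radius_mi = 10,
                       distant_monitor_city = NULL,
                       seed = 1L) {
  mode <- match.arg(mode)

  counts <- list(n_cities = n_cities, subjects_per_city = subjects_per_city,
                 months_per_subject = months_per_subject,
                 days_per_month_sampled = days_per_month_sampled)
  for (nm in names(counts)) {
    v <- counts[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v != round(v)) {
      abort(sprintf("`%s` must be a single integer >= 1 (got %s).",
                    nm, deparse(v)))
    }
  }
  if (days_per_month_sampled > 28) {
    abort("`days_per_month_sampled` must be <= 28 (days are drawn from 1-28).")
  }

  sds <- list(sigma_city = sigma_city, sigma_subject = sigma_subject,
              sigma_slope_city = sigma_slope_city, sigma_w = sigma_w,
              ambient_sd = ambient_sd, ambient_daily_sd = ambient_daily_sd,
              sulfate_ratio_sd = sulfate_ratio_sd,
              nonambient_sd = nonambient_sd, monitor_error_sd = monitor_error_sd,
              model_pred_error_sd = model_pred_error_sd)
  for (nm in names(sds)) {
    v <- sds[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      abort(sprintf("`%s` must be a single non-negative number (got %s).",
                    nm, deparse(v)))
    }
  }

  if (!is.numeric(age_range) || length(age_range) != 2L || age_range[1] > age_range[2]) {
    abort("`age_range` must be a non-decreasing numeric pair.")
  }
  if (minor_fraction < 0 || minor_fraction >= 1) {
    abort("`minor_fraction` must be in [0, 1).")
  }
  if (!is.null(distant_monitor_city) &&
      (distant_monitor_city < 1 || distant_monitor_city > n_cities)) {
    abort("`distant_monitor_city` must index an existing city.")
  }

  structure(
    list(n_cities = as.integer(n_cities),
         subjects_per_city = as.integer(subjects_per_city),
         months_per_subject = as.integer(months_per_subject),
         days_per_month_sampled = as.integer(days_per_month_sampled),
         gamma0 = gamma0, gamma1_true = gamma1_true,
         gamma2_true = gamma2_true, gamma4_true = gamma4_true,
         gamma4_covariate = gamma4_covariate,
         sigma_city = sigma_city, sigma_subject = sigma_subject,
         sigma_slope_city = sigma_slope_city, sigma_w = sigma_w,
         ambient_mean = ambient_mean, ambient_sd = ambient_sd,
         ambient_daily_sd = ambient_daily_sd,
         sulfate_ratio_mean = sulfate_ratio_mean,
         sulfate_ratio_sd = sulfate_ratio_sd,
         nonambient_mean = nonambient_mean, nonambient_sd = nonambient_sd,
         monitor_error_sd = monitor_error_sd,
         model_pred_error_sd = model_pred_error_sd,
         mode = mode, age_range = age_range,
         minor_fraction = minor_fraction,
         residence_radius_mi = residence_radius_mi,
         distant_monitor_city = distant_monitor_city,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> mode:", x$mode, "\n")
  cat(sprintf("  design: %d cities x %d subjects x %d months (%d days/month)\n",
              x$n_cities, x$subjects_per_city, x$months_per_subject,
              x$days_per_month_sampled))
  cat(sprintf("  truth: gamma0 = %g, gamma1 = %g, gamma2 = %g, gamma4 = %g\n",
              x$gamma0, x$gamma1_true, x$gamma2_true, x$gamma4_true))
  cat(sprintf("  sd: city %g, subject %g, slope %g, residual %g\n",
              x$sigma_city, x$sigma_subject, x$sigma_slope_city, x$sigma_w))
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# exact truncated-normal draw via inverse CDF (deterministic given the seed)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(pmin(upper, pmax(lower, rep(mean, n))))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}
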