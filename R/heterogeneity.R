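#' Boundary-mixture p-value for a variance-component LRT
#'
#' The null hypothesis that a variance component is zero lies on the
#' boundary of the parameter space, so the likelihood-ratio statistic is
#' referred to a 50:50 mixture of a point mass at zero and chi-square with
#' 1 df: the p-value is 0.5 when the estimated component is zero (LRT = 0),
#' and `0.5 * (1 - pchisq(LRT, 1))` otherwise.
#'
#' @param lrt Likelihood-ratio statistic(s), must be >= 0. A negative value
#'   signals an upstream fitting fault and is rejected, not clamped.
#' @param boundary Logical: was the variance component estimated at zero?
#' @return The mixture p-value(s).
#' @export
#' @examples
#' mixture_lrt_p(0, boundary = TRUE)   # 0.5
#' mixture_lrt_p(2.705543)             # ~0.05
mixture_lrt_p <- function(lrt, boundary = FALSE) {
  if (any(!is.finite(lrt)) || any(lrt < 0)) {
    abort("`lrt` must be non-negative and finite (negative values indicate an upstream fitting fault).")
  }
  ifelse(boundary | lrt == 0, 0.5,
         0.5 * pchisq(lrt, df = 1, lower.tail = FALSE))
}

#' Test between-city heterogeneity of the calibration coefficient
#'
#' Compares the model with a city random slope (`model1`) to the model
#' without it (`model2`) by a REML likelihood-ratio test (the fixed effects
#' are identical, so REML likelihoods are comparable) and refers the
#' statistic to the 50:50 boundary mixture ([mixture_lrt_p()]).
#' Small negative statistics within optimizer tolerance (1e-6) are clipped
#' to zero and treated as the boundary case.
#'
#' @inheritParams fit_calibration
#' @param ... Passed to [fit_calibration()] for both fits.
#' @return A list of class `calib_het`: `lrt`, `p_value`, `boundary`,
#'   `sigma2_slope_city`, and the two fits.
#' @export
heterogeneity_test <- function(data,
                               true_exposure = c("ambient_origin", "total_personal"),
                               surrogate = c("monitor", "model_pred"),
                               ...) {
  n_cities <- n_distinct(data$city_id)
  if (n_cities < 3) {
    warn(sprintf("Heterogeneity testing with %d cities is weakly informative; >= 3 recommended.",
                 n_cities))
  }
  m1 <- fit_calibration(data, model = "model1", true_exposure = true_exposure,
                        surrogate = surrogate, ...)
  m2 <- fit_calibration(data, model = "model2", true_exposure = true_exposure,
                        surrogate = surrogate, ...)
  if (!m1$converged) abort("Model 1 (with city random slope) did not converge.")
  if (!m2$converged) abort("Model 2 (without city random slope) did not converge.")
  if (m1$loglik_reml < m2$loglik_reml - 1e-10) {
    # nesting says ll1 >= ll2: the slope-model optimizer stopped short
    m1 <- refit_best_optimum(m1)
  }
  res <- finish_het(m1, m2)
  structure(c(res, list(fit_model1 = m1, fit_model2 = m2)),
            class = "calib_het")
}

# shared LRT assembly for heterogeneity_test and residual-heterogeneity checks
finish_het <- function(m_slope, m_noslope) {
  lrt <- 2 * (m_slope$loglik_reml - m_noslope$loglik_reml)
  if (is.na(lrt)) { # ML fits
    lrt <- 2 * (m_slope$loglik_ml - m_noslope$loglik_ml)
  }
  if (lrt < 0) {
    if (lrt < -1e-6) {
      abort(sprintf("Negative LRT (%.3g) beyond optimizer tolerance: the slope model is not at its optimum.",
                    lrt))
    }
    lrt <- 0
  }
  boundary <- ("sigma2_slope_city" %in% m_slope$boundary_flags) || lrt == 0
  list(lrt = lrt, p_value = mixture_lrt_p(lrt, boundary), boundary = boundary,
       sigma2_slope_city = m_slope$sigma2_slope_city)
}

#' @export
print.calib_het <- function(x, ...) {
  cat(sprintf("<calib_het> LRT = %.4f, mixture p = %.4g%s\n",
              x$lrt, x$p_value,
              if (x$boundary) " (boundary: slope variance estimated at 0)" else ""))
  cat(sprintf("  sigma2_slope_city = %.5g\n", x$sigma2_slope_city))
  invisible(x)
}

#' Predicted shift of a city's calibration coefficient
#'
#' Applies a city-covariate interaction coefficient (per raw covariate unit)
#' to a covariate change: a shift of `delta` units changes the city's
#' calibration coefficient by `gamma4 * delta`.
#'
#' @param gamma4 Interaction coefficient (per raw covariate unit).
#' @param delta Covariate change, in raw units.
#' @return `gamma4 * delta`.
#' @export
#' @examples
#' predict_coef_shift(-2.53, 0.1)  # -0.253: ~0.25 decrease
predict_coef_shift <- function(gamma4, delta) {
  gamma4 * delta
}

#' Forward stepwise selection of city covariates
#'
#' Searches for city-level variables explaining between-city heterogeneity
#' in the calibration coefficient. At each step every remaining candidate is
#' added to the covariate-interaction model (`model3`) and the candidate
#' whose surrogate-by-covariate interaction has the smallest Wald p-value
#' below `alpha` enters; selection stops when none qualifies. Residual
#' heterogeneity after selection is assessed by the boundary-mixture LRT of
#' the city random slope in the final model.
#'
#' Candidates must be constant within city and take at least two distinct
#' values across the fitted cities; with few cities, candidates that are
#' (near-)collinear with already-selected ones are skipped with a warning.
#'
#' @inheritParams fit_calibration
#' @param candidates Character vector of candidate covariate names in
#'   `covariate_data`.
#' @param alpha Entry threshold (default 0.05).
#' @param standardize Z-score covariates across cities before fitting
#'   (default TRUE); the returned scaling permits predictions for new
#'   cities on the same scale.
#' @param ... Passed to [fit_calibration()].
#' @return A list of class `calib_stepwise`: `selected`, `path` (per-step
#'   candidate p-values), `final_fit` (a `model3` fit, or the `model1` fit
#'   when nothing is selected), `residual_lrt`, `residual_p`,
#'   `residual_boundary`, `scaling`.
#' @export
stepwise_city_covariates <- function(data, covariate_data, candidates,
                                     true_exposure = c("ambient_origin", "total_personal"),
                                     surrogate = c("monitor", "model_pred"),
                                     alpha = 0.05,
                                     standardize = TRUE,
                                     ...) {
  check_columns(covariate_data, c("city_id", candidates), "covariate_data")
  cities <- unique(as.character(data$city_id))
  cov_city <- covariate_data %>%
    mutate(city_id = as.character(.data$city_id)) %>%
    filter(.data$city_id %in% cities)

  usable <- character(0)
  for (cd in candidates) {
    v <- cov_city[[cd]]
    if (n_distinct(v) < 2) {
      warn(sprintf("Candidate '%s' has fewer than 2 distinct values across cities; dropped.", cd))
    } else {
      usable <- c(usable, cd)
    }
  }

  selected <- character(0)
  path <- list()
  step <- 0L
  repeat {
    remaining <- setdiff(usable, selected)
    if (length(remaining) == 0) break
    step <- step + 1L
    pvals <- purrr::map_dbl(remaining, function(cd) {
      trial <- c(selected, cd)
      M <- scale(as.matrix(cov_city[trial]))
      if (qr(cbind(1, M))$rank < length(trial) + 1L) {
        warn(sprintf("Candidate '%s' is collinear with already-selected covariates across these cities; skipped.", cd))
        return(NA_real_)
      }
      f <- fit_calibration(data, model = "model3",
                           true_exposure = true_exposure,
                           surrogate = surrogate,
                           covariate_data = cov_city,
                           city_covariates = trial,
                           standardize_covariates = standardize, ...)
      it <- paste0("z:", cd)
      2 * pnorm(-abs(f$gamma[[it]] / sqrt(f$vcov_gamma[it, it])))
    })
    path[[step]] <- tibble(step = step, candidate = remaining, p_value = pvals)
    if (all(is.na(pvals)) || min(pvals, na.rm = TRUE) >= alpha) break
    selected <- c(selected, remaining[which.min(pvals)])
  }

  if (length(selected)) {
    final_fit <- fit_calibration(data, model = "model3",
                                 true_exposure = true_exposure,
                                 surrogate = surrogate,
                                 covariate_data = cov_city,
                                 city_covariates = selected,
                                 standardize_covariates = standardize, ...)
    no_slope <- fit_calibration(data, model = "model3",
                                true_exposure = true_exposure,
                                surrogate = surrogate,
                                covariate_data = cov_city,
                                city_covariates = selected,
                                standardize_covariates = standardize,
                                random_slope = FALSE, ...)
  } else {
    final_fit <- fit_calibration(data, model = "model1",
                                 true_exposure = true_exposure,
                                 surrogate = surrogate, ...)
    no_slope <- fit_calibration(data, model = "model2",
                                true_exposure = true_exposure,
                                surrogate = surrogate, ...)
  }
  if (final_fit$loglik_reml < no_slope$loglik_reml - 1e-10) {
    final_fit <- refit_best_optimum(final_fit)
  }
  res <- finish_het(final_fit, no_slope)

  structure(list(selected = selected,
                 path = bind_rows(path),
                 final_fit = final_fit,
                 residual_lrt = res$lrt,
                 residual_p = res$p_value,
                 residual_boundary = res$boundary,
                 scaling = final_fit$scaling,
                 alpha = alpha),
            class = "calib_stepwise")
}

#' @export
print.calib_stepwise <- function(x, ...) {
  cat("<calib_stepwise> selected:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)",
      "\n")
  cat(sprintf("  residual heterogeneity: LRT = %.4f, mixture p = %.4g\n",
              x$residual_lrt, x$residual_p))
  invisible(x)
}

#' City-specific calibration coefficients (per-city mixed fits)
#'
#' Fits each city's own calibration model (subject random intercepts only)
#' and returns the per-city coefficients with Wald intervals and
#' inverse-variance weights for forest-plot rendering. Undersized cities and
#' cities with a constant surrogate are flagged and excluded from estimation
#' with a note rather than an error.
#'
#' @inheritParams fit_calibration
#' @param alpha CI level (default 0.05).
#' @param min_subjects,min_months Minimum subjects and distinct months a
#'   city needs to be fitted.
#' @param ... Passed to [fit_calibration()].
#' @return A tibble of class `calib_city_fits`: `city_id`, `gamma1`, `se`,
#'   `ci_low`, `ci_high`, `weight` (1/se^2), `n_subjects`,
#'   `n_person_months`, `converged`, `note`.
#' @export
city_specific_fits <- function(data,
                               true_exposure = c("ambient_origin", "total_personal"),
                               surrogate = c("monitor", "model_pred"),
                               alpha = 0.05,
                               min_subjects = 2, min_months = 2,
                               ...) {
  true_exposure <- match.arg(true_exposure)
  surrogate <- match.arg(surrogate)
  xcol <- switch(true_exposure, ambient_origin = "x_ambient_origin",
                 total_personal = "x_total_personal")
  zcol <- switch(surrogate, monitor = "z_monitor", model_pred = "z_model_pred")
  zq <- qnorm(1 - alpha / 2)

  cities <- sort(unique(as.character(data$city_id)))
  rows <- purrr::map_dfr(cities, function(ci) {
    d <- data[as.character(data$city_id) == ci &
                !is.na(data[[xcol]]) & !is.na(data[[zcol]]), ]
    base <- tibble(city_id = ci, gamma1 = NA_real_, se = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_, weight = NA_real_,
                   n_subjects = n_distinct(d$subject_id),
                   n_person_months = nrow(d),
                   converged = NA, note = NA_character_)
    if (base$n_subjects < min_subjects ||
        n_distinct(paste(d$year, d$month)) < min_months) {
      base$note <- "excluded: too few subjects or months"
      return(base)
    }
    if (n_distinct(d[[zcol]]) < 2) {
      base$note <- "non-identifiable: constant surrogate within city"
      return(base)
    }
    use_season <- n_distinct(d$season) > 1
    f <- tryCatch(
      fit_calibration(d, model = "model4", true_exposure = true_exposure,
                      surrogate = surrogate, city = ci, season = use_season,
                      ...),
      error = function(e) e)
    if (inherits(f, "error")) {
      base$note <- paste("fit failed:", conditionMessage(f))
      return(base)
    }
    base$gamma1 <- f$gamma[["z"]]
    base$se <- sqrt(f$vcov_gamma["z", "z"])
    base$ci_low <- base$gamma1 - zq * base$se
    base$ci_high <- base$gamma1 + zq * base$se
    base$weight <- 1 / base$se^2
    base$converged <- f$converged
    if (!use_season) base$note <- "single season: season term dropped"
    if (any(grepl("nonidentifiable", f$boundary_flags))) {
      base$note <- paste(stats::na.omit(c(base$note,
        "one observation per subject: subject/residual variance not separable")),
        collapse = "; ")
    }
    base
  })
  class(rows) <- c("calib_city_fits", class(rows))
  rows
}

#' Leave-one-city-out cross-validation of the covariate selection
#'
#' Validates the city-covariate meta-regression: each city is held out in
#' turn, stepwise selection and the covariate-interaction model are re-run
#' on the remaining cities, and the omitted city's calibration coefficient
#' is predicted from its own covariate values,
#' \eqn{\hat\gamma_{1i}^- = \hat\gamma_{1(-i)} + \sum_c \hat\gamma_{4c(-i)}
#' \mathrm{CityVariable}_{ci}} (covariates on the training scale). Predicted
#' coefficients are compared with the observed city-specific coefficients
#' from the per-city fits by their correlation, the mean relative bias
#' \eqn{(\hat\gamma_{1i}^- - \hat\gamma_{1i})/\hat\gamma_{1i}} and the mean
#' absolute value of that ratio, averaged over cities.
#'
#' The left-out city's observations never enter selection or fitting; this
#' is asserted on the training index set for every fold.
#'
#' @inheritParams stepwise_city_covariates
#' @param correlation `"pearson"` (default) or `"spearman"`.
#' @param ... Passed to [fit_calibration()].
#' @return A list of class `calib_loocv`: `per_city` (observed, predicted,
#'   selected covariates, training-fold details), `correlation`,
#'   `mean_relative_bias`, `mean_absolute_bias`, `n_used`, `n_failed`.
#' @export
loocv_city_coefficients <- function(data, covariate_data, candidates,
                                    true_exposure = c("ambient_origin", "total_personal"),
                                    surrogate = c("monitor", "model_pred"),
                                    alpha = 0.05,
                                    standardize = TRUE,
                                    correlation = c("pearson", "spearman"),
                                    ...) {
  correlation <- match.arg(correlation)
  cities <- sort(unique(as.character(data$city_id)))
  if (length(cities) < 3) abort("LOOCV requires at least 3 cities.")
  cov_city <- mutate(covariate_data, city_id = as.character(.data$city_id))

  observed <- suppressWarnings(
    city_specific_fits(data, true_exposure = true_exposure,
                       surrogate = surrogate, alpha = alpha, ...))

  folds <- purrr::map_dfr(cities, function(ci) {
    train <- data[as.character(data$city_id) != ci, ]
    train_cities <- unique(as.character(train$city_id))
    # hard guarantee: the held-out city contributes nothing to training
    stopifnot(!(ci %in% train_cities),
              length(train_cities) == length(cities) - 1L)
    out <- tibble(city_id = ci, predicted = NA_real_,
                  selected = NA_character_,
                  n_training_cities = length(train_cities),
                  training_excludes_city = TRUE,
                  reason = NA_character_)
    sw <- tryCatch(
      suppressWarnings(stepwise_city_covariates(
        train, filter(cov_city, .data$city_id != ci), candidates,
        true_exposure = true_exposure, surrogate = surrogate,
        alpha = alpha, standardize = standardize, ...)),
      error = function(e) e)
    if (inherits(sw, "error")) {
      out$reason <- paste("stepwise failed:", conditionMessage(sw))
      return(out)
    }
    g1 <- sw$final_fit$gamma[["z"]]
    pred <- g1
    if (length(sw$selected)) {
      covs_i <- cov_city[cov_city$city_id == ci, sw$selected, drop = FALSE]
      for (cd in sw$selected) {
        v <- covs_i[[cd]]
        if (!is.null(sw$scaling)) {
          v <- (v - sw$scaling$center[[cd]]) / sw$scaling$scale[[cd]]
        }
        pred <- pred + sw$final_fit$gamma[[paste0("z:", cd)]] * v
      }
    }
    out$predicted <- pred
    out$selected <- paste(sw$selected, collapse = ";")
    out
  })

  per_city <- observed %>%
    as_tibble() %>%
    select("city_id", observed = "gamma1", obs_se = "se", "note") %>%
    left_join(folds, by = "city_id")

  m <- loocv_metrics(per_city$predicted, per_city$observed,
                     correlation = correlation)
  structure(c(list(per_city = per_city), m,
              list(correlation_method = correlation)),
            class = "calib_loocv")
}

#' Cross-validation summary metrics
#'
#' Compares predicted with observed city-specific calibration coefficients:
#' their correlation, the mean relative bias
#' `mean((predicted - observed)/observed)` and the mean absolute bias
#' `mean(|...|)`, over cities with both values available (observed values of
#' exactly zero are excluded, since the ratio is undefined there).
#'
#' @param predicted,observed Numeric vectors of equal length.
#' @param correlation `"pearson"` or `"spearman"`.
#' @return List with `correlation`, `mean_relative_bias`,
#'   `mean_absolute_bias`, `n_used`, `n_failed`.
#' @export
#' @examples
#' loocv_metrics(c(0.5, 0.5), c(0.4, 0.6))
loocv_metrics <- function(predicted, observed,
                          correlation = c("pearson", "spearman")) {
  correlation <- match.arg(correlation)
  stopifnot(length(predicted) == length(observed))
  ok <- !is.na(observed) & !is.na(predicted) & observed != 0
  rel <- (predicted[ok] - observed[ok]) / observed[ok]
  list(correlation = if (sum(ok) >= 2)
         suppressWarnings(cor(predicted[ok], observed[ok],
                              method = correlation)) # NA if degenerate
       else NA_real_,
       mean_relative_bias = mean(rel),
       mean_absolute_bias = mean(abs(rel)),
       n_used = sum(ok),
       n_failed = sum(!ok))
}

#' @export
print.calib_loocv <- function(x, ...) {
  cat(sprintf("<calib_loocv> %d cities used (%d failed/excluded)\n",
              x$n_used, x$n_failed))
  cat(sprintf("  correlation (%s) = %.3f\n", x$correlation_method,
              x$correlation))
  cat(sprintf("  mean relative bias = %.4f, mean absolute bias = %.4f\n",
              x$mean_relative_bias, x$mean_absolute_bias))
  invisible(x)
}
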