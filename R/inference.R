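#' Wald test of the calibration coefficient against 1
#'
#' Tests the no-attenuation hypothesis that the calibration coefficient
#' equals 1 using the Wald statistic
#' \eqn{(\hat\gamma_1 - 1)^2 / \widehat{var}(\hat\gamma_1) \sim \chi^2_1}.
#'
#' @param gamma1_hat Estimated calibration coefficient(s).
#' @param var_gamma1 Estimated variance(s) of `gamma1_hat` (must be > 0).
#' @param null Null value (default 1).
#' @return A list with `statistic` and `p_value` (upper-tail chi-square, 1 df).
#' @export
#' @examples
#' wald_gamma1_test(1, 0.01)$p_value   # 1 at the null value
#' wald_gamma1_test(0, 1)$p_value      # ~0.317
wald_gamma1_test <- function(gamma1_hat, var_gamma1, null = 1) {
  if (any(!is.finite(var_gamma1)) || any(var_gamma1 <= 0)) {
    abort("`var_gamma1` must be positive and finite.")
  }
  stat <- (gamma1_hat - null)^2 / var_gamma1
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Seasonal effect modification of the calibration coefficient
#'
#' Augments the calibration model with a surrogate-by-season interaction and
#' tests it at level `alpha`. When the interaction is significant,
#' season-stratified coefficients are reported: with winter coded 1, the
#' summer coefficient is the surrogate main effect and the winter coefficient
#' adds the interaction, with delta-method confidence intervals from the
#' fixed-effect covariance (or, with `stratified_method = "refit"`, from
#' separate per-season fits).
#'
#' @inheritParams fit_calibration
#' @param alpha Significance level (default 0.05).
#' @param stratified_method `"delta"` (linear combination of the interaction
#'   fit) or `"refit"` (independent per-season fits).
#' @param ... Passed to [fit_calibration()].
#' @return A list of class `calib_season`: `report` (the season-adjusted
#'   main-model [calibration_report()] row), `interaction_p`,
#'   `season_stratified` (tibble with per-season estimate and CI, or `NULL`
#'   when the interaction is not significant), and the two fits.
#' @export
season_modification <- function(data,
                                true_exposure = c("ambient_origin", "total_personal"),
                                surrogate = c("monitor", "model_pred"),
                                model = "model1",
                                alpha = 0.05,
                                stratified_method = c("delta", "refit"),
                                ...) {
  stratified_method <- match.arg(stratified_method)
  if (n_distinct(data$season) < 2) {
    abort("Both seasons must be present to assess seasonal modification.")
  }
  main <- fit_calibration(data, model = model, true_exposure = true_exposure,
                          surrogate = surrogate, ...)
  inter <- fit_calibration(data, model = model, true_exposure = true_exposure,
                           surrogate = surrogate, season_interaction = TRUE,
                           ...)
  est_i <- inter$gamma[["z:winter"]]
  se_i <- sqrt(inter$vcov_gamma["z:winter", "z:winter"])
  p_int <- 2 * pnorm(-abs(est_i / se_i))

  stratified <- NULL
  if (p_int < alpha) {
    zq <- qnorm(1 - alpha / 2)
    if (stratified_method == "delta") {
      vg <- inter$vcov_gamma
      summer_est <- inter$gamma[["z"]]
      summer_se <- sqrt(vg["z", "z"])
      winter_est <- inter$gamma[["z"]] + est_i
      winter_se <- sqrt(vg["z", "z"] + vg["z:winter", "z:winter"] +
                          2 * vg["z", "z:winter"])
      stratified <- tibble(
        season = c("winter", "summer"),
        estimate = c(winter_est, summer_est),
        se = c(winter_se, summer_se))
    } else {
      one <- function(s) {
        f <- fit_calibration(filter(data, .data$season == s), model = model,
                             true_exposure = true_exposure,
                             surrogate = surrogate, season = FALSE, ...)
        tibble(season = s, estimate = f$gamma[["z"]],
               se = sqrt(f$vcov_gamma["z", "z"]))
      }
      stratified <- bind_rows(one("winter"), one("summer"))
    }
    stratified <- mutate(stratified,
                         ci_low = .data$estimate - zq * .data$se,
                         ci_high = .data$estimate + zq * .data$se)
  }

  structure(list(report = calibration_report(main, alpha = alpha),
                 interaction_p = p_int,
                 season_stratified = stratified,
                 fit_main = main, fit_interaction = inter,
                 alpha = alpha),
            class = "calib_season")
}

#' @export
print.calib_season <- function(x, ...) {
  r <- x$report
  cat(sprintf("<calib_season> gamma1 = %.3f (%.3f, %.3f), p1 = %.3g\n",
              r$gamma1_hat, r$ci_low, r$ci_high, r$p_value_1))
  cat(sprintf("  season interaction p = %.3g (%ssignificant at %.2g)\n",
              x$interaction_p,
              if (x$interaction_p < x$alpha) "" else "not ", x$alpha))
  if (!is.null(x$season_stratified)) {
    print(x$season_stratified)
  }
  invisible(x)
}

#' Subgroup effect modification of the calibration coefficient
#'
#' Same mechanics as [season_modification()] with a binary subject-level
#' flag (e.g. seniors, COPD, MI, CHD) replacing season in the interaction:
#' for each flag the model adds `surrogate x flag`, tests the interaction,
#' and reports stratified coefficients by delta method.
#'
#' @inheritParams season_modification
#' @param flags Character vector naming logical/0-1 columns of `data`.
#' @return A tibble with one row per flag: `flag`, `interaction_p`,
#'   `estimate_flag0`, `estimate_flag1`, their standard errors and
#'   `ci_low`/`ci_high` columns, and `significant`.
#' @export
subgroup_interaction <- function(data, flags,
                                 true_exposure = c("ambient_origin", "total_personal"),
                                 surrogate = c("monitor", "model_pred"),
                                 model = "model1",
                                 alpha = 0.05,
                                 ...) {
  check_columns(data, flags, "data")
  zq <- qnorm(1 - alpha / 2)
  purrr::map_dfr(flags, function(fl) {
    v <- as.numeric(data[[fl]])
    if (n_distinct(v[!is.na(v)]) < 2) {
      abort(sprintf("Flag '%s' is constant; both levels must be represented.",
                    fl))
    }
    fit <- fit_calibration(data, model = model, true_exposure = true_exposure,
                           surrogate = surrogate, interaction_term = fl, ...)
    it <- paste0("z:", fl)
    est_i <- fit$gamma[[it]]
    se_i <- sqrt(fit$vcov_gamma[it, it])
    p_int <- 2 * pnorm(-abs(est_i / se_i))
    vg <- fit$vcov_gamma
    e0 <- fit$gamma[["z"]]
    s0 <- sqrt(vg["z", "z"])
    e1 <- e0 + est_i
    s1 <- sqrt(vg["z", "z"] + vg[it, it] + 2 * vg["z", it])
    tibble(flag = fl, interaction_p = p_int,
           estimate_flag0 = e0, se_flag0 = s0,
           ci_low_flag0 = e0 - zq * s0, ci_high_flag0 = e0 + zq * s0,
           estimate_flag1 = e1, se_flag1 = s1,
           ci_low_flag1 = e1 - zq * s1, ci_high_flag1 = e1 + zq * s1,
           significant = p_int < alpha)
  })
}
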