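#' Fit a calibration mixed model
#'
#' Regresses the "true" monthly personal exposure on a surrogate exposure by
#' REML (or ML), with the hierarchical random-effects structure of multi-city
#' panel validation studies:
#' \describe{
#'   \item{`model1`}{city random intercept, city random slope on the
#'     surrogate (independent of the intercept), subject random intercept
#'     nested in city, iid residual. The fixed slope on the surrogate is the
#'     pooled calibration coefficient.}
#'   \item{`model2`}{`model1` without the city random slope; the comparison
#'     model for the between-city heterogeneity test.}
#'   \item{`model3`}{`model1` plus city-level covariate main effects and
#'     their interactions with the surrogate (meta-regression on city
#'     characteristics).}
#'   \item{`model4`}{a single-city fit with subject random intercepts only,
#'     giving that city's own calibration coefficient.}
#' }
#' Season is coded winter = 1 (October--March), summer = 0, so the fixed
#' surrogate slope is the summer-season slope when a season interaction is
#' included. The subject random intercept induces compound-symmetry
#' (exchangeable) correlation among a subject's repeated months.
#'
#' @param data Monthly analysis table from [build_analysis_table()] (needs
#'   `city_id`, `subject_id`, `season` and the exposure columns). Rows with
#'   missing true or surrogate exposure are dropped with a message.
#' @param model One of `"model1"`, `"model2"`, `"model3"`, `"model4"`.
#' @param true_exposure `"ambient_origin"` (column `x_ambient_origin`) or
#'   `"total_personal"` (column `x_total_personal`).
#' @param surrogate `"monitor"` (column `z_monitor`) or `"model_pred"`
#'   (column `z_model_pred`).
#' @param covariate_data City covariate table (`city_id` plus covariate
#'   columns); required for `model3`.
#' @param city_covariates Character vector of covariate names for `model3`.
#' @param city City id for `model4`.
#' @param season Include the fixed season term (default TRUE).
#' @param season_interaction Add the surrogate-by-season interaction.
#' @param interaction_term Optional name of a column in `data` (e.g. a
#'   subgroup flag) to interact with the surrogate.
#' @param estimation `"REML"` (default) or `"ML"`.
#' @param standardize_covariates For `model3`, z-score covariates across
#'   cities before fitting (default TRUE). Use FALSE for per-raw-unit
#'   interaction coefficients.
#' @param random_slope Override the model's default random-slope choice
#'   (used internally for residual-heterogeneity tests).
#' @param verbose Message the number of dropped rows.
#' @return An object of class `calib_fit`: fixed effects `gamma` with
#'   covariance `vcov_gamma`, variance components `sigma2_city`,
#'   `sigma2_subject`, `sigma2_slope_city`, `sigma2_w`, log-likelihoods,
#'   sample sizes, convergence and boundary flags, and the underlying
#'   \pkg{lme4} fit.
#' @export
#' @examples
#' panel <- simulate_panel(sim_config(n_cities = 4, subjects_per_city = 8,
#'                                    months_per_subject = 4, seed = 2))
#' tab <- build_analysis_table(panel$daily, panel$monitors, panel$model_pred,
#'                             verbose = FALSE)
#' fit <- fit_calibration(tab, "model1", "total_personal", "monitor")
#' fit$gamma[["z"]]
fit_calibration <- function(data,
                            model = c("model1", "model2", "model3", "model4"),
                            true_exposure = c("ambient_origin", "total_personal"),
                            surrogate = c("monitor", "model_pred"),
                            covariate_data = NULL,
                            city_covariates = NULL,
                            city = NULL,
                            season = TRUE,
                            season_interaction = FALSE,
                            interaction_term = NULL,
                            estimation = c("REML", "ML"),
                            standardize_covariates = TRUE,
                            random_slope = NULL,
                            verbose = FALSE) {
  model <- match.arg(model)
  true_exposure <- match.arg(true_exposure)
  surrogate <- match.arg(surrogate)
  estimation <- match.arg(estimation)

  xcol <- switch(true_exposure, ambient_origin = "x_ambient_origin",
                 total_personal = "x_total_personal")
  zcol <- switch(surrogate, monitor = "z_monitor", model_pred = "z_model_pred")
  check_columns(data, c("city_id", "subject_id", "season", xcol, zcol),
                "data")

  df <- tibble(
    city_id = as.character(data$city_id),
    subject_uid = paste(data$city_id, data$subject_id, sep = ":"),
    x = data[[xcol]],
    z = data[[zcol]],
    winter = as.numeric(data$season == "winter"))
  if (!is.null(interaction_term)) {
    check_columns(data, interaction_term, "data")
    df[[interaction_term]] <- as.numeric(data[[interaction_term]])
  }

  if (model == "model4") {
    if (is.null(city)) abort("`model4` requires a `city` id.")
    df <- filter(df, .data$city_id == city)
    if (nrow(df) == 0) abort(sprintf("No rows for city '%s'.", city))
  }

  scaling <- NULL
  if (model == "model3") {
    if (is.null(city_covariates) || length(city_covariates) == 0) {
      abort("`model3` requires at least one city covariate.")
    }
    if (is.null(covariate_data)) abort("`model3` requires `covariate_data`.")
    check_columns(covariate_data, c("city_id", city_covariates),
                  "covariate_data")
    cov_use <- covariate_data %>%
      mutate(city_id = as.character(.data$city_id)) %>%
      filter(.data$city_id %in% unique(df$city_id)) %>%
      select(dplyr::all_of(c("city_id", city_covariates)))
    if (standardize_covariates) {
      scaling <- list(
        center = vapply(cov_use[city_covariates], mean, numeric(1)),
        scale = vapply(cov_use[city_covariates], sd, numeric(1)))
      if (any(scaling$scale == 0 | is.na(scaling$scale))) {
        abort(sprintf("City covariate(s) constant across cities: %s.",
                      paste(city_covariates[scaling$scale == 0 |
                                              is.na(scaling$scale)],
                            collapse = ", ")))
      }
      for (cv in city_covariates) {
        cov_use[[cv]] <- (cov_use[[cv]] - scaling$center[[cv]]) /
          scaling$scale[[cv]]
      }
    }
    df <- left_join(df, cov_use, by = "city_id")
  }

  keep <- complete.cases(df)
  if (any(!keep)) {
    if (verbose) {
      inform(sprintf("Dropping %d row(s) with missing values.", sum(!keep)))
    }
    df <- df[keep, ]
  }
  if (nrow(df) == 0) abort("No complete observations to fit.")

  n_cities <- n_distinct(df$city_id)
  if (model != "model4" && n_cities < 2) {
    abort(sprintf("`%s` requires data from at least 2 cities (got %d).",
                  model, n_cities))
  }

  # fixed-effect design
  fterms <- "z"
  if (season) fterms <- c(fterms, "winter")
  if (model == "model3") {
    fterms <- c(fterms, city_covariates,
                paste0("z:", city_covariates))
  }
  if (season_interaction) fterms <- c(fterms, "z:winter")
  if (!is.null(interaction_term)) {
    fterms <- c(fterms, interaction_term, paste0("z:", interaction_term))
  }
  fixed_rhs <- paste(fterms, collapse = " + ")
  mm <- model.matrix(as.formula(paste("~", fixed_rhs)), df)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    dep <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    abort(sprintf("Fixed-effect design is rank deficient; collinear column(s): %s.",
                  paste(dep, collapse = ", ")))
  }

  if (is.null(random_slope)) {
    random_slope <- model %in% c("model1", "model3")
  }
  rterms <- "(1 | subject_uid)"
  if (model != "model4") rterms <- c("(1 | city_id)", rterms)
  if (random_slope && model != "model4") {
    rterms <- c(rterms, "(0 + z | city_id)")
  }
  fml <- as.formula(paste("x ~", fixed_rhs, "+",
                          paste(rterms, collapse = " + ")))

  fitted <- fit_lmer_robust(fml, df, reml = estimation == "REML")
  meta <- list(model = model, true_exposure = true_exposure,
               surrogate = surrogate, estimation = estimation,
               random_slope = random_slope,
               city_covariates = if (model == "model3") city_covariates else NULL,
               scaling = scaling, city = city, formula = fml)
  build_calib_fit(fitted$fit, fitted$converged, fitted$messages, meta)
}

# assemble the calib_fit object from a fitted merMod
build_calib_fit <- function(fit, converged, messages, meta) {
  df <- fit@frame
  model <- meta$model
  random_slope <- meta$random_slope
  estimation <- meta$estimation
  gamma <- lme4::fixef(fit)
  vg <- as.matrix(vcov(fit))
  vc <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(grp_prefix, var1) {
    i <- startsWith(vc$grp, grp_prefix) &
      (is.na(var1) | (!is.na(vc$var1) & vc$var1 == var1))
    if (!any(i)) return(NA_real_)
    vc$vcov[which(i)[1]]
  }
  sigma2_subject <- pick("subject_uid", "(Intercept)")
  sigma2_city <- if (model == "model4") NA_real_ else pick("city_id", "(Intercept)")
  sigma2_slope_city <- if (random_slope && model != "model4")
    pick("city_id", "z") else NA_real_
  sigma2_w <- vc$vcov[vc$grp == "Residual"]

  bthr <- 1e-8 * max(var(df$x), .Machine$double.eps)
  comps <- c(sigma2_city = sigma2_city, sigma2_subject = sigma2_subject,
             sigma2_slope_city = sigma2_slope_city, sigma2_w = sigma2_w)
  boundary_flags <- names(comps)[!is.na(comps) & comps < bthr]

  # one observation per subject leaves subject and residual variance
  # unseparated (model 4 degenerate case)
  max_rep <- max(table(df$subject_uid))
  if (max_rep == 1L) {
    boundary_flags <- union(boundary_flags, "sigma2_subject/sigma2_w_nonidentifiable")
  }

  ll <- as.numeric(logLik(fit))
  structure(list(
    gamma = gamma,
    vcov_gamma = vg,
    sigma2_city = sigma2_city,
    sigma2_subject = sigma2_subject,
    sigma2_slope_city = sigma2_slope_city,
    sigma2_w = sigma2_w,
    loglik_reml = if (estimation == "REML") ll else NA_real_,
    loglik_ml = if (estimation == "ML") ll else NA_real_,
    n_obs = nrow(df),
    n_subjects = n_distinct(df$subject_uid),
    n_cities = if ("city_id" %in% names(df)) n_distinct(df$city_id) else 1L,
    converged = converged,
    boundary_flags = boundary_flags,
    diagnostics = messages,
    model = model, true_exposure = meta$true_exposure,
    surrogate = meta$surrogate,
    estimation = estimation, random_slope = random_slope,
    city_covariates = meta$city_covariates,
    scaling = meta$scaling, city = meta$city,
    formula = meta$formula,
    fit = fit),
    class = "calib_fit")
}

# refit from alternative optimizers and keep the best restricted likelihood;
# used when a nested comparison reveals the first optimum was not reached
refit_best_optimum <- function(cf) {
  df <- cf$fit@frame
  best <- cf
  for (opt in c("bobyqa", "Nelder_Mead")) {
    alt <- tryCatch(suppressWarnings(suppressMessages(
      lme4::lmer(cf$formula, data = df, REML = cf$estimation == "REML",
                 control = lme4::lmerControl(
                   optimizer = opt,
                   check.conv.grad = lme4::.makeCC("warning", tol = 2e-2))))),
      error = function(e) NULL)
    if (is.null(alt)) next
    meta <- cf[c("model", "true_exposure", "surrogate", "estimation",
                 "random_slope", "city_covariates", "scaling", "city",
                 "formula")]
    cand <- build_calib_fit(alt, TRUE, character(0), meta)
    ll_best <- max(best$loglik_reml, best$loglik_ml, na.rm = TRUE)
    ll_cand <- max(cand$loglik_reml, cand$loglik_ml, na.rm = TRUE)
    if (ll_cand > ll_best) best <- cand
  }
  best
}

# lmer with captured warnings and a bobyqa retry on optimizer failure;
# non-convergence is reported via the flag, never raised
fit_lmer_robust <- function(fml, df, reml) {
  one <- function(optimizer) {
    msgs <- character(0)
    args <- list(check.conv.grad = lme4::.makeCC("warning", tol = 2e-2),
                 # degenerate designs (one obs/subject) are flagged, not fatal
                 check.nobs.vs.nlev = "ignore", check.nobs.vs.nRE = "ignore")
    if (!is.null(optimizer)) args$optimizer <- optimizer
    ctrl <- do.call(lme4::lmerControl, args)
    fit <- withCallingHandlers(
      lme4::lmer(fml, data = df, REML = reml, control = ctrl),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m))
        invokeRestart("muffleMessage")
      })
    ok <- isTRUE(fit@optinfo$conv$opt == 0) &&
      !any(grepl("failed to converge", msgs))
    list(fit = fit, converged = ok, messages = msgs)
  }
  r <- one(NULL)
  if (!r$converged) {
    r2 <- one("bobyqa")
    better <- as.numeric(logLik(r2$fit)) >= as.numeric(logLik(r$fit)) - 1e-8
    if (r2$converged || (better && !r$converged)) r <- r2
  }
  r
}

#' @export
print.calib_fit <- function(x, ...) {
  cat(sprintf("<calib_fit> %s | true: %s | surrogate: %s | %s\n",
              x$model, x$true_exposure, x$surrogate, x$estimation))
  g1 <- x$gamma[["z"]]
  se <- sqrt(x$vcov_gamma["z", "z"])
  cat(sprintf("  calibration coefficient gamma1 = %.3f (95%% CI %.3f, %.3f)\n",
              g1, g1 - qnorm(0.975) * se, g1 + qnorm(0.975) * se))
  cat(sprintf("  var comps: city %.4g, subject %.4g, slope(city) %.4g, residual %.4g\n",
              x$sigma2_city, x$sigma2_subject, x$sigma2_slope_city, x$sigma2_w))
  cat(sprintf("  n = %d person-months, %d subjects, %d cities; converged: %s\n",
              x$n_obs, x$n_subjects, x$n_cities, x$converged))
  if (length(x$boundary_flags)) {
    cat("  boundary:", paste(x$boundary_flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Marginal covariance implied by the calibration random effects
#'
#' Materializes the dense covariance matrix of the observation vector under
#' the model's random effects: a city-intercept block, a subject-intercept
#' block, a city-slope term contributing `z_a * z_b` within city, and an iid
#' residual. Used as the algebraic oracle for the REML fits.
#'
#' @param city,subject Grouping vectors (length n).
#' @param z Surrogate values (length n).
#' @param sigma2_city,sigma2_subject,sigma2_slope_city,sigma2_w Non-negative
#'   variance components.
#' @return The n x n symmetric PSD covariance matrix.
#' @export
#' @examples
#' marginal_covariance(rep(1, 3), rep(1, 3), rep(0, 3), 0, 1, 0, 1)
marginal_covariance <- function(city, subject, z, sigma2_city, sigma2_subject,
                                sigma2_slope_city = 0, sigma2_w = 1) {
  comps <- c(sigma2_city, sigma2_subject, sigma2_slope_city, sigma2_w)
  if (any(is.na(comps)) || any(comps < 0)) {
    abort("Variance components must be non-negative.")
  }
  n <- length(z)
  stopifnot(length(city) == n, length(subject) == n)
  same_city <- outer(city, city, "==") * 1
  same_subj <- outer(paste(city, subject), paste(city, subject), "==") * 1
  sigma2_city * same_city + sigma2_subject * same_subj +
    sigma2_slope_city * (z %o% z) * same_city + sigma2_w * diag(n)
}

#' Summarize the pooled calibration coefficient of a fit
#'
#' Extracts the calibration coefficient (the fixed slope on the surrogate),
#' its Wald 95% confidence interval, and the Wald p-value against the
#' no-attenuation null (slope = 1).
#'
#' @param fit A `calib_fit`.
#' @param alpha Significance level for the CI (default 0.05).
#' @param null Null value tested (default 1).
#' @return A one-row tibble: `model`, `true_exposure`, `surrogate`,
#'   `gamma1_hat`, `se`, `ci_low`, `ci_high`, `p_value_1`, `n_obs`,
#'   `n_subjects`, `n_cities`.
#' @export
calibration_report <- function(fit, alpha = 0.05, null = 1) {
  stopifnot(inherits(fit, "calib_fit"))
  g1 <- fit$gamma[["z"]]
  v <- fit$vcov_gamma["z", "z"]
  zq <- qnorm(1 - alpha / 2)
  tibble(model = fit$model, true_exposure = fit$true_exposure,
         surrogate = fit$surrogate,
         gamma1_hat = g1, se = sqrt(v),
         ci_low = g1 - zq * sqrt(v), ci_high = g1 + zq * sqrt(v),
         p_value_1 = wald_gamma1_test(g1, v, null = null)$p_value,
         n_obs = fit$n_obs, n_subjects = fit$n_subjects,
         n_cities = fit$n_cities)
}
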