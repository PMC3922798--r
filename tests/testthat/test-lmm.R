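test_that("fixed effects equal the closed-form GLS solution at the estimated variance components", {
  for (seed in c(1, 2, 3)) {
    tab <- toy_table(n_cities = 2, n_subjects = 2, n_months = 3, seed = seed)
    f <- suppressWarnings(fit_calibration(tab, "model1", "total_personal",
                                          "monitor"))
    V <- marginal_covariance(tab$city_id, tab$subject_id, tab$z_monitor,
                             f$sigma2_city, f$sigma2_subject,
                             max(f$sigma2_slope_city, 0), f$sigma2_w)
    X <- cbind(1, tab$z_monitor, as.numeric(tab$season == "winter"))
    y <- tab$x_total_personal
    expect_equal(unname(f$gamma), gls_beta(X, y, V), tolerance = 1e-8)
    expect_equal(unname(f$vcov_gamma),
                 unname(solve(t(X) %*% solve(V) %*% X)), tolerance = 1e-8)
    expect_equal(f$loglik_reml, dense_reml_loglik(X, y, V), tolerance = 1e-8)
  }
})

test_that("the REML criterion matches a dense-matrix likelihood over a grid of variance components", {
  tab <- toy_table(n_cities = 2, n_subjects = 2, n_months = 3, seed = 5)
  f <- suppressWarnings(fit_calibration(tab, "model1", "total_personal",
                                        "monitor"))
  devf <- lme4::lmer(f$formula, data = f$fit@frame, REML = TRUE,
                     devFunOnly = TRUE)
  thn <- names(lme4::getME(f$fit, "theta"))
  X <- cbind(1, tab$z_monitor, as.numeric(tab$season == "winter"))
  y <- tab$x_total_personal
  n <- nrow(X); p <- ncol(X)
  # theta entries are sds relative to the residual sd, named by term
  grid <- expand.grid(subj = c(0.3, 1), city = c(0, 0.7), slope = c(0, 0.05))
  for (i in seq_len(nrow(grid))) {
    th <- numeric(3)
    th[grep("subject_uid", thn)] <- grid$subj[i]
    th[setdiff(grep("city_id", thn), grep("z", thn))] <- grid$city[i]
    th[grep("z", thn)] <- grid$slope[i]
    # dense profiled REML criterion at the same relative components
    Vrel <- marginal_covariance(tab$city_id, tab$subject_id, tab$z_monitor,
                                grid$city[i]^2, grid$subj[i]^2,
                                grid$slope[i]^2, 1)
    Vi <- solve(Vrel)
    beta <- gls_beta(X, y, Vrel)
    r <- y - X %*% beta
    s2 <- drop(t(r) %*% Vi %*% r) / (n - p)
    crit <- (n - p) * (1 + log(2 * pi * s2)) +
      as.numeric(determinant(Vrel)$modulus) +
      as.numeric(determinant(t(X) %*% Vi %*% X)$modulus)
    expect_equal(devf(th), crit, tolerance = 1e-8)
  }
})

test_that("marginal covariance matches its closed forms and a Monte-Carlo oracle", {
  # residual only
  expect_equal(marginal_covariance(1:3, 1:3, rep(0, 3), 0, 0, 0, 2),
               2 * diag(3))
  # one subject, three observations: compound symmetry with ICC 1/2
  V <- marginal_covariance(rep(1, 3), rep(1, 3), rep(0, 3), 0, 1, 0, 1)
  expect_equal(V, matrix(1, 3, 3) + diag(3))
  expect_error(marginal_covariance(1:2, 1:2, c(0, 0), -1, 0, 0, 1),
               "non-negative")
  # Monte-Carlo: simulate the random effects directly
  set.seed(8)
  city <- c(1, 1, 1, 2); subj <- c(1, 1, 2, 1); z <- c(0.5, -1, 2, 1)
  s2c <- 0.6; s2s <- 1.2; s2g <- 0.4; s2w <- 0.9
  V <- marginal_covariance(city, subj, z, s2c, s2s, s2g, s2w)
  nrep <- 200000
  g1 <- matrix(rnorm(2 * nrep, 0, sqrt(s2c)), nrep)
  g3 <- matrix(rnorm(2 * nrep, 0, sqrt(s2g)), nrep)
  g2 <- matrix(rnorm(3 * nrep, 0, sqrt(s2s)), nrep)
  suid <- c(1, 1, 2, 3)
  Y <- g1[, city] + g2[, suid] + g3[, city] * rep(z, each = nrep) +
    matrix(rnorm(4 * nrep, 0, sqrt(s2w)), nrep)
  expect_equal(unname(cov(Y)), unname(V), tolerance = 0.05)
})

test_that("degenerate generation without random effects reduces to the fixed-effect truth", {
  qt <- quick_panel_table(n_cities = 5, subjects_per_city = 20,
                          months_per_subject = 6,
                          sigma_city = 0, sigma_subject = 0,
                          sigma_slope_city = 0, sigma_w = 3, seed = 19)
  f <- suppressWarnings(fit_calibration(qt$tab, "model1", "total_personal",
                                        "monitor"))
  tr <- qt$panel$truth
  # 3 Monte-Carlo standard errors
  expect_lt(abs(f$gamma[["z"]] - tr$gamma1_true),
            3 * sqrt(f$vcov_gamma["z", "z"]))
  expect_lt(abs(f$gamma[["(Intercept)"]] - tr$gamma0),
            3 * sqrt(f$vcov_gamma["(Intercept)", "(Intercept)"]))
  expect_lt(abs(f$gamma[["winter"]] - tr$gamma2_true),
            3 * sqrt(f$vcov_gamma["winter", "winter"]))
  expect_lt(f$sigma2_city, 0.5)
  expect_lt(f$sigma2_slope_city, 0.01)
})

test_that("adding the city random slope never decreases the REML log-likelihood", {
  for (seed in 1:5) {
    qt <- quick_panel_table(n_cities = 4, subjects_per_city = 6,
                            months_per_subject = 4, seed = seed)
    m1 <- suppressWarnings(fit_calibration(qt$tab, "model1",
                                           "total_personal", "monitor"))
    m2 <- suppressWarnings(fit_calibration(qt$tab, "model2",
                                           "total_personal", "monitor"))
    expect_gte(m1$loglik_reml, m2$loglik_reml - 1e-6)
  }
})

test_that("estimates are equivariant under scaling of X and centering of Z", {
  qt <- quick_panel_table(n_cities = 4, subjects_per_city = 8,
                          months_per_subject = 4, seed = 23)
  tab <- qt$tab
  f0 <- suppressWarnings(fit_calibration(tab, "model1", "total_personal",
                                         "monitor"))
  tab_s <- dplyr::mutate(tab, x_total_personal = 3 * x_total_personal)
  fs <- suppressWarnings(fit_calibration(tab_s, "model1", "total_personal",
                                         "monitor"))
  expect_equal(unname(fs$gamma), unname(3 * f0$gamma), tolerance = 1e-3)
  expect_equal(fs$sigma2_w, 9 * f0$sigma2_w, tolerance = 1e-3)
  expect_equal(fs$sigma2_subject, 9 * f0$sigma2_subject, tolerance = 1e-2)
  # centering invariance holds for the model without the city random slope
  # (an uncorrelated random slope makes the covariance depend on the origin
  # of Z, so model 1 is not centering-invariant by construction)
  f0b <- suppressWarnings(fit_calibration(tab, "model2", "total_personal",
                                          "monitor"))
  zbar <- mean(tab$z_monitor)
  tab_c <- dplyr::mutate(tab, z_monitor = z_monitor - zbar)
  fc <- suppressWarnings(fit_calibration(tab_c, "model2", "total_personal",
                                         "monitor"))
  expect_equal(fc$gamma[["z"]], f0b$gamma[["z"]], tolerance = 1e-3)
  expect_equal(fc$gamma[["winter"]], f0b$gamma[["winter"]], tolerance = 1e-3)
  expect_equal(fc$gamma[["(Intercept)"]],
               f0b$gamma[["(Intercept)"]] + zbar * f0b$gamma[["z"]],
               tolerance = 1e-3)
})

test_that("single-season data with a season term is rejected naming the column", {
  tab <- toy_table(seed = 2)
  tab$season <- "summer"
  expect_error(fit_calibration(tab, "model1", "total_personal", "monitor"),
               "winter")
})

test_that("model 4 equals a subject-intercept fit on one city and flags the one-observation degeneracy", {
  tab <- toy_table(n_cities = 3, n_subjects = 4, n_months = 4, seed = 6)
  f4 <- suppressWarnings(fit_calibration(tab, "model4", "total_personal",
                                         "monitor", city = "c01"))
  expect_equal(f4$n_cities, 1L)
  expect_true(is.na(f4$sigma2_city))
  expect_true(is.na(f4$sigma2_slope_city))
  # one observation per subject: variance partition not identifiable
  tab1 <- dplyr::filter(tab, month_index == 1)
  f41 <- suppressWarnings(fit_calibration(tab1, "model4", "total_personal",
                                          "monitor", city = "c01",
                                          season = FALSE))
  expect_true(any(grepl("nonidentifiable", f41$boundary_flags)))
})

test_that("REML and ML log-likelihoods are stored according to the estimation method", {
  tab <- toy_table(seed = 3)
  fr <- suppressWarnings(fit_calibration(tab, "model2", "total_personal",
                                         "monitor"))
  fm <- suppressWarnings(fit_calibration(tab, "model2", "total_personal",
                                         "monitor", estimation = "ML"))
  expect_false(is.na(fr$loglik_reml)); expect_true(is.na(fr$loglik_ml))
  expect_false(is.na(fm$loglik_ml)); expect_true(is.na(fm$loglik_reml))
})

test_that("tidy and glance return broom-shaped summaries", {
  tab <- toy_table(seed = 4)
  f <- suppressWarnings(fit_calibration(tab, "model1", "total_personal",
                                        "monitor"))
  td <- tidy(f, conf.int = TRUE)
  expect_named(td, c("term", "estimate", "std.error", "statistic",
                     "conf.low", "conf.high"))
  expect_true("z" %in% td$term)
  vp <- tidy(f, effects = "ran_pars")
  expect_equal(nrow(vp), 4)
  g <- glance(f)
  expect_equal(g$nobs, f$n_obs)
  expect_true(is.logical(g$converged))
})
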