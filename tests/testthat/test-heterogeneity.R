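test_that("boundary mixture p-value follows the 50:50 rule", {
  expect_identical(mixture_lrt_p(0, boundary = TRUE), 0.5)
  expect_identical(mixture_lrt_p(0), 0.5)
  expect_equal(mixture_lrt_p(2.705543), 0.05, tolerance = 1e-6)
  expect_equal(mixture_lrt_p(qchisq(0.8, 1)), 0.1, tolerance = 1e-12)
  expect_error(mixture_lrt_p(-0.01), "non-negative")
})

test_that("mixture p-value is continuous and strictly decreasing, approaching 0.5 at zero", {
  lrt <- seq(1e-8, 10, length.out = 200)
  p <- mixture_lrt_p(lrt)
  expect_true(all(diff(p) < 0))
  expect_equal(p[1], 0.5, tolerance = 1e-4)
  expect_true(all(p > 0 & p <= 0.5))
})

test_that("heterogeneity test hits the boundary on homogeneous-slope data and detects strong heterogeneity", {
  qt0 <- quick_panel_table(n_cities = 4, subjects_per_city = 6,
                           months_per_subject = 4, sigma_slope_city = 0,
                           sigma_w = 4, seed = 2)
  het0 <- suppressWarnings(heterogeneity_test(qt0$tab, "total_personal",
                                              "monitor"))
  expect_true(het0$boundary)
  expect_identical(het0$p_value, 0.5)
  expect_equal(het0$lrt, 0, tolerance = 1e-6)
  qt1 <- quick_panel_table(n_cities = 8, subjects_per_city = 15,
                           months_per_subject = 6, sigma_slope_city = 0.5,
                           seed = 2)
  het1 <- suppressWarnings(heterogeneity_test(qt1$tab, "total_personal",
                                              "monitor"))
  expect_lt(het1$p_value, 0.001)
  expect_false(het1$boundary)
})

test_that("covariate-shift prediction is gamma4 times delta", {
  expect_equal(round(predict_coef_shift(-2.53, 0.1), 2), -0.25)
  expect_equal(predict_coef_shift(17, 0), 0)
  expect_equal(predict_coef_shift(2, 0.5), 1)
})

test_that("stepwise selection finds a generating covariate and heterogeneity is explained after adjustment", {
  # city slopes driven entirely by vehicles_per_unit (raw-scale gamma4)
  qt <- quick_panel_table(n_cities = 12, subjects_per_city = 15,
                          months_per_subject = 6,
                          sigma_slope_city = 0, gamma4_true = 0.5,
                          gamma4_covariate = "vehicles_per_unit", seed = 4)
  covars <- qt$panel$city_covariates
  het <- suppressWarnings(heterogeneity_test(qt$tab, "total_personal",
                                             "monitor"))
  expect_lt(het$p_value, 0.05) # covariate-driven slope spread looks heterogeneous
  sw <- suppressWarnings(stepwise_city_covariates(
    qt$tab, covars, c("vehicles_per_unit", "heating_degree_days",
                      "residents_per_unit"),
    "total_personal", "monitor"))
  expect_true("vehicles_per_unit" %in% sw$selected)
  expect_gt(sw$residual_p, het$p_value) # adjustment removes the heterogeneity
  # raw-scale fit reproduces the generating interaction coefficient
  fraw <- suppressWarnings(fit_calibration(
    qt$tab, "model3", "total_personal", "monitor",
    covariate_data = covars, city_covariates = "vehicles_per_unit",
    standardize_covariates = FALSE))
  expect_lt(abs(fraw$gamma[["z:vehicles_per_unit"]] - 0.5),
            3 * sqrt(fraw$vcov_gamma["z:vehicles_per_unit",
                                     "z:vehicles_per_unit"]))
})

test_that("stepwise drops unusable candidates with a warning", {
  qt <- quick_panel_table(n_cities = 5, subjects_per_city = 6,
                          months_per_subject = 4, seed = 6)
  covars <- qt$panel$city_covariates
  covars$flat <- 1 # constant across cities
  expect_warning(
    sw <- suppressMessages(stepwise_city_covariates(
      qt$tab, covars, c("flat", "vehicles_per_unit"),
      "total_personal", "monitor")),
    "fewer than 2 distinct")
  expect_false("flat" %in% sw$selected)
})

test_that("city-specific fits report per-city slopes with precision weights and flag degenerate cities", {
  qt <- quick_panel_table(n_cities = 5, subjects_per_city = 10,
                          months_per_subject = 6, sigma_slope_city = 0,
                          seed = 8)
  cf <- suppressWarnings(city_specific_fits(qt$tab, "total_personal",
                                            "monitor"))
  expect_equal(nrow(cf), 5)
  expect_true(all(!is.na(cf$gamma1)))
  expect_equal(cf$weight, 1 / cf$se^2)
  # homogeneous generation: estimates scatter consistently with their SEs
  q_stat <- sum((cf$gamma1 - weighted.mean(cf$gamma1, cf$weight))^2 *
                  cf$weight)
  expect_lt(q_stat, qchisq(0.999, df = 4))
  # constant surrogate within a city is flagged, not fitted
  tab2 <- qt$tab
  tab2$z_monitor[tab2$city_id == "city01"] <- 10
  cf2 <- suppressWarnings(city_specific_fits(tab2, "total_personal",
                                             "monitor"))
  expect_true(is.na(cf2$gamma1[cf2$city_id == "city01"]))
  expect_match(cf2$note[cf2$city_id == "city01"], "constant surrogate")
  # undersized city is excluded with a note
  tab3 <- dplyr::filter(qt$tab, city_id != "city02" |
                          subject_id %in% "s001")
  cf3 <- suppressWarnings(city_specific_fits(tab3, "total_personal",
                                             "monitor"))
  expect_match(cf3$note[cf3$city_id == "city02"], "too few")
})

test_that("LOOCV metrics match hand-computed values and perfect prediction", {
  m <- loocv_metrics(c(0.4, 0.6), c(0.4, 0.6))
  expect_equal(m$correlation, 1)
  expect_equal(m$mean_relative_bias, 0)
  expect_equal(m$mean_absolute_bias, 0)
  # predictions {0.5, 0.5} vs observed {0.4, 0.6}
  m2 <- loocv_metrics(c(0.5, 0.5), c(0.4, 0.6))
  expect_equal(m2$mean_relative_bias, (0.25 - 1 / 6) / 2, tolerance = 1e-12)
  expect_equal(m2$mean_absolute_bias, (0.25 + 1 / 6) / 2, tolerance = 1e-12)
})

test_that("absolute bias always dominates the relative bias in magnitude", {
  set.seed(14)
  for (i in 1:20) {
    pred <- rnorm(6, 0.5, 0.3)
    obs <- rnorm(6, 0.5, 0.3)
    obs[abs(obs) < 0.05] <- 0.05
    m <- loocv_metrics(pred, obs)
    expect_gte(m$mean_absolute_bias, abs(m$mean_relative_bias) - 1e-12)
  }
})

test_that("leave-one-city-out predictions never use the held-out city and track a strong covariate signal", {
  qt <- quick_panel_table(n_cities = 12, subjects_per_city = 15,
                          months_per_subject = 6,
                          sigma_slope_city = 0, gamma4_true = 0.5, seed = 4)
  lv <- suppressWarnings(loocv_city_coefficients(
    qt$tab, qt$panel$city_covariates,
    c("vehicles_per_unit", "heating_degree_days", "residents_per_unit"),
    "total_personal", "monitor"))
  expect_equal(nrow(lv$per_city), 12)
  expect_true(all(lv$per_city$training_excludes_city))
  expect_true(all(lv$per_city$n_training_cities == 11))
  expect_gt(lv$correlation, 0.3)
  expect_error(loocv_city_coefficients(
    dplyr::filter(qt$tab, city_id %in% c("city01", "city02")),
    qt$panel$city_covariates, "vehicles_per_unit",
    "total_personal", "monitor"), "at least 3")
})
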