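test_that("sulfate tracer arithmetic and missingness behave as specified", {
  expect_equal(ambient_origin_tracer(2, 2, 15), 15)
  expect_equal(ambient_origin_tracer(1, 2, 20), 10)
  # cohort-level plausibility: mean ratio times mean monitor concentration
  expect_equal(round(ambient_origin_tracer(0.64, 1, 15.86), 2), 10.15)
  expect_message(out <- ambient_origin_tracer(c(1, 1), c(0, NA), c(10, 10)),
                 "ambient sulfate")
  expect_true(all(is.na(out)))
  expect_error(ambient_origin_tracer(-1, 2, 10), "non-negative")
})

test_that("tracer is linear in ambient PM2.5 and personal sulfate, and bounded by ambient for ratios <= 1", {
  set.seed(4)
  ps <- runif(50, 0, 3); as <- runif(50, 0.5, 4); pm <- runif(50, 1, 40)
  expect_equal(ambient_origin_tracer(ps, as, 2 * pm),
               2 * ambient_origin_tracer(ps, as, pm))
  expect_equal(ambient_origin_tracer(3 * ps, as, pm),
               3 * ambient_origin_tracer(ps, as, pm))
  ratio_le1 <- pmin(ps, as)
  expect_true(all(ambient_origin_tracer(ratio_le1, as, pm) <= pm + 1e-12))
})

test_that("time-weighted ambient-origin estimate interpolates between indoor and outdoor", {
  expect_equal(ambient_origin_timeweighted(20, 0.5, 1), 10)
  expect_equal(ambient_origin_timeweighted(20, 0.5, 0), 20)
  expect_equal(ambient_origin_timeweighted(20, 0.6, 0.5), 16)
  expect_error(ambient_origin_timeweighted(20, 0.5, 1.2), "time_fraction")
  expect_error(ambient_origin_timeweighted(20, 2, 0.5), "infiltration")
})

test_that("season assignment partitions the calendar", {
  expect_identical(assign_season(10), "winter")
  expect_identical(assign_season(4), "summer")
  expect_identical(assign_season(12), "winter")
  s <- assign_season(1:12)
  expect_identical(sort(which(s == "winter")), c(1:3, 10:12))
  expect_identical(sort(which(s == "summer")), 4:9)
  expect_true(all(s %in% c("winter", "summer")))
  expect_error(assign_season(0), "1..12")
  expect_error(assign_season(13), "1..12")
})

test_that("haversine distance matches the spherical-law-of-cosines oracle and is a metric", {
  set.seed(11)
  n <- 1000
  la1 <- runif(n, -60, 60); lo1 <- runif(n, -170, 170)
  la2 <- la1 + runif(n, -2, 2); lo2 <- lo1 + runif(n, -2, 2)
  d <- haversine_mi(la1, lo1, la2, lo2)
  expect_equal(d, slc_mi(la1, lo1, la2, lo2), tolerance = 1e-6)
  expect_equal(d, haversine_mi(la2, lo2, la1, lo1)) # symmetric
  expect_true(all(d >= 0))
  expect_equal(haversine_mi(la1, lo1, la1, lo1), rep(0, n))
  expect_error(haversine_mi(95, 0, 0, 0), "coordinates")
})

test_that("nearest-monitor matching applies the distance cap and deterministic tie-break", {
  mons <- tibble::tibble(monitor_id = c("m_far", "m_near", "m_mid"),
                         lat = c(41, 40.05, 40.12), lon = c(-75, -75, -75))
  hit <- nearest_monitor(40, -75, mons)
  expect_identical(hit$monitor_id, "m_near")
  self <- nearest_monitor(40.05, -75, mons)
  expect_identical(self$monitor_id, "m_near")
  expect_equal(self$distance_mi, 0)
  none <- nearest_monitor(35, -75, mons, max_distance_mi = 30)
  expect_true(is.na(none$monitor_id))
  # exact tie: two monitors mirrored about the residence -> lexicographic id
  tie <- nearest_monitor(40, -75, tibble::tibble(
    monitor_id = c("b", "a"), lat = c(40.1, 39.9), lon = c(-75, -75)))
  expect_identical(tie$monitor_id, "a")
  expect_error(nearest_monitor(40, -75, mons[0, ]), "one monitor")
})

test_that("monthly monitor averages differ between all-days and matched-days modes", {
  dates <- seq(as.Date("2000-06-01"), as.Date("2000-06-10"), by = "day")
  ser <- tibble::tibble(date = dates, ambient_pm25 = 1:10)
  expect_equal(monthly_monitor_average(ser, 2000, 6, "all_days"), 5.5)
  expect_equal(monthly_monitor_average(ser, 2000, 6, "matched_days",
                                       personal_days = dates[c(1, 3)]), 2)
  cst <- tibble::tibble(date = dates, ambient_pm25 = 7)
  expect_equal(monthly_monitor_average(cst, 2000, 6, "all_days"), 7)
  expect_equal(monthly_monitor_average(cst, 2000, 6, "matched_days",
                                       personal_days = dates[2:4]), 7)
  expect_true(is.na(monthly_monitor_average(ser, 2000, 7, "all_days")))
})

test_that("analysis table has one row per eligible subject-month with correct means", {
  dates <- as.Date(c("2000-01-03", "2000-01-08", "2000-02-04"))
  daily <- tibble::tibble(
    city_id = "c1", subject_id = rep(c("s1", "s2"), each = 3),
    date = rep(dates, 2), age = rep(c(70, 17), each = 3),
    personal_pm25 = c(10, 20, 30, 1, 2, 3),
    personal_so4 = c(1, 3, 2, NA, NA, NA),
    ambient_so4 = c(4, 4, 4, 4, 4, 4),
    lat = 40, lon = -75, time_fraction_indoors = 0.8)
  mons <- tibble::tibble(
    monitor_id = "m1", lat = 40.01, lon = -75,
    date = seq(as.Date("2000-01-01"), as.Date("2000-02-28"), by = "day"))
  mons$ambient_pm25 <- ifelse(format(mons$date, "%m") == "01", 12, 18)
  tab <- build_analysis_table(daily, mons, verbose = FALSE)
  # the 17-year-old is excluded entirely
  expect_false("s2" %in% tab$subject_id)
  expect_equal(nrow(tab), 2) # s1: Jan + Feb
  jan <- tab[tab$month == 1, ]
  expect_equal(jan$x_total_personal, 15)
  expect_equal(jan$n_personal_days, 2L)
  # tracer: ratio of monthly means (2/4) times matched-days monitor mean (12)
  expect_equal(jan$x_ambient_origin, 0.5 * 12)
  expect_equal(jan$z_monitor, 12) # all-days mean
  expect_identical(jan$season, "winter")
  expect_equal(jan$month_index, 1L)
})

test_that("row count equals eligible subjects times qualifying months", {
  qt <- quick_panel_table(n_cities = 4, subjects_per_city = 6,
                          months_per_subject = 5, seed = 31)
  expect_equal(nrow(qt$tab), 4 * 6 * 5)
  # min-day rule: requiring more days than sampled drops everything
  tab2 <- build_analysis_table(qt$panel$daily, qt$panel$monitors,
                               qt$panel$model_pred,
                               min_days_per_month = 8, verbose = FALSE)
  expect_equal(nrow(tab2), 0)
})

test_that("missing sulfate propagates to the tracer exposure only", {
  qt0 <- quick_panel_table(n_cities = 2, subjects_per_city = 4,
                           months_per_subject = 2, seed = 17)
  daily <- qt0$panel$daily
  drop_subj <- daily$subject_id == "s001"
  daily$personal_so4[drop_subj] <- NA
  tab <- build_analysis_table(daily, qt0$panel$monitors,
                              qt0$panel$model_pred, verbose = FALSE)
  expect_true(all(is.na(tab$x_ambient_origin[tab$subject_id == "s001"])))
  expect_true(all(!is.na(tab$x_total_personal)))
  expect_true(all(!is.na(tab$x_ambient_origin[tab$subject_id != "s001"])))
})

test_that("matched-days monitor mode falls back to the nearest monitor with data", {
  dates <- seq(as.Date("2000-06-01"), as.Date("2000-06-07"), by = "day")
  daily <- tibble::tibble(
    city_id = "c1", subject_id = "s1", date = dates, age = 60,
    personal_pm25 = 10, personal_so4 = 1, ambient_so4 = 2,
    lat = 40, lon = -75, time_fraction_indoors = 0.8)
  mons <- dplyr::bind_rows(
    tibble::tibble(monitor_id = "near", lat = 40.01, lon = -75,
                   date = dates[1:3], ambient_pm25 = 10),
    tibble::tibble(monitor_id = "backup", lat = 40.2, lon = -75,
                   date = dates, ambient_pm25 = 30))
  tab <- build_analysis_table(daily, mons, monitor_mode = "matched_days",
                              verbose = FALSE)
  # 3 days at the near monitor (10), 4 fallback days at the backup (30)
  expect_equal(tab$z_monitor, (3 * 10 + 4 * 30) / 7)
})

test_that("schema violations name the offending column", {
  daily <- tibble::tibble(city_id = "a", subject_id = "s")
  expect_error(build_analysis_table(daily, tibble::tibble()), "date")
})
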