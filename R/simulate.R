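#' Simulate a multi-city personal-exposure panel study
#'
#' Generates a complete synthetic validation-study dataset with known ground
#' truth: daily subject records (personal PM2.5 and personal/ambient sulfate),
#' a daily city-monitor series, monthly outdoor-home model predictions, and a
#' city covariate table. Subjects are monitored over consecutive calendar
#' months with staggered start months, so both seasons are represented.
#'
#' In `"regression_truth"` mode the monthly true exposure is drawn exactly
#' from the calibration mixed model
#' \deqn{X_{ijk} = (\gamma_0 + g_{1i} + g_{2ij}) + (\gamma_1 + g_{3i}) Z_{ijk}
#'   + \gamma_2 \mathrm{Winter}_{ijk} + \varepsilon_{ijk},}
#' with \eqn{Z_{ijk}} the all-days monthly mean of the city monitor; daily
#' personal values and sulfate concentrations are constructed so the monthly
#' analysis table reproduces \eqn{X_{ijk}} exactly. In `"mechanistic"` mode
#' personal exposure of ambient origin is the subject's infiltration ratio
#' times the city-month ambient level, total exposure adds a non-ambient
#' source, and monitors and model predictions observe the ambient level with
#' error.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `pm_panel` with elements `daily`, `monitors`,
#'   `model_pred`, `city_covariates` (tibbles), `truth` (named list of every
#'   configured parameter plus realized quantities), and `config`.
#' @export
#' @examples
#' panel <- simulate_panel(sim_config(n_cities = 3, subjects_per_city = 4,
#'                                    months_per_subject = 2, seed = 11))
#' dplyr::glimpse(panel$daily)
simulate_panel <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created with sim_config().")
  }
  set.seed(config$seed)
  I <- config$n_cities
  J <- config$subjects_per_city
  K <- config$months_per_subject
  D <- config$days_per_month_sampled

  # --- geography: city centroids spread across a continental grid
  city <- tibble(
    city_idx = seq_len(I),
    city_id = sprintf("city%02d", seq_len(I)),
    c_lat = 30 + 2.5 * ((seq_len(I) - 1) %% 8),
    c_lon = -118 + 6 * (seq_len(I) - 1))

  monitor_offset_mi <- rep(2, I)
  if (!is.null(config$distant_monitor_city)) {
    monitor_offset_mi[config$distant_monitor_city] <- 45
  }
  monitor_loc <- tibble(
    monitor_id = paste0("mon_", city$city_id),
    city_id = city$city_id,
    lat = city$c_lat + monitor_offset_mi / 69,
    lon = city$c_lon)

  covars <- tibble(
    city_id = city$city_id,
    vehicles_per_unit = runif(I, 1.0, 2.2),
    heating_degree_days = runif(I, 1500, 7000),
    residents_per_unit = runif(I, 2.0, 3.0))

  # --- subjects: residence, age, infiltration ratio, sampling window
  subj <- tidyr::expand_grid(city_idx = seq_len(I), snum = seq_len(J)) %>%
    left_join(city, by = "city_idx") %>%
    mutate(subject_id = sprintf("s%03d", .data$snum))
  ns <- nrow(subj)
  rr <- config$residence_radius_mi * sqrt(runif(ns))
  th <- runif(ns, 0, 2 * pi)
  subj$lat <- subj$c_lat + rr * cos(th) / 69
  subj$lon <- subj$c_lon + rr * sin(th) / (69 * cos(subj$c_lat * pi / 180))
  subj$age <- runif(ns, config$age_range[1], config$age_range[2])
  if (config$minor_fraction > 0) {
    is_minor <- runif(ns) < config$minor_fraction
    subj$age[is_minor] <- runif(sum(is_minor), 10, 17.5)
  }
  subj$ratio <- rtruncnorm(ns, config$sulfate_ratio_mean,
                           config$sulfate_ratio_sd, 0, 1.5)
  subj$time_fraction_indoors <- runif(ns, 0.6, 0.95)
  subj$start_month <- sample.int(12, ns, replace = TRUE)
  subj$g2 <- rnorm(ns, 0, config$sigma_subject)

  # --- city random effects
  g1 <- rnorm(I, 0, config$sigma_city)
  g3 <- rnorm(I, 0, config$sigma_slope_city)

  # --- subject-month grid (calendar months of year 2000 onward)
  sm <- tidyr::expand_grid(row = seq_len(ns), k = seq_len(K))
  sm <- dplyr::bind_cols(subj[sm$row, c("city_idx", "city_id", "subject_id",
                                        "ratio", "g2", "start_month")],
                         sm["k"])
  cal <- sm$start_month + sm$k - 1L
  sm$year <- 2000L + (cal - 1L) %/% 12L
  sm$month <- (cal - 1L) %% 12L + 1L
  sm$winter <- as.integer(sm$month %in% c(10:12, 1:3))

  # --- city-month ambient field and daily monitor series
  cm <- distinct(sm, .data$city_idx, .data$city_id, .data$year, .data$month) %>%
    arrange(.data$city_idx, .data$year, .data$month)
  cm$ambient <- pmax(1, rnorm(nrow(cm), config$ambient_mean, config$ambient_sd))
  cm$ndays <- days_in_month(cm$year, cm$month)

  cm$month_start <- as.Date(sprintf("%d-%02d-01", cm$year, cm$month))
  mon <- cm[rep(seq_len(nrow(cm)), cm$ndays), ]
  mon$day <- sequence(cm$ndays)
  mon$date <- mon$month_start + (mon$day - 1L)
  # day-to-day ambient deviation, shared by monitor and personal exposure
  mon$a_day <- pmax(0, mon$ambient +
                      rnorm(nrow(mon), 0, config$ambient_daily_sd))
  mon$ambient_pm25 <- pmax(0, mon$a_day +
                             rnorm(nrow(mon), 0, config$monitor_error_sd))
  monitors <- mon %>%
    left_join(monitor_loc, by = "city_id") %>%
    select("monitor_id", "lat", "lon", "date", "ambient_pm25") %>%
    as_tibble()

  # all-days monthly monitor mean: the surrogate used to generate X
  zall <- mon %>%
    group_by(.data$city_id, .data$year, .data$month) %>%
    summarise(z_gen = mean(.data$ambient_pm25), .groups = "drop")

  sm <- sm %>%
    left_join(cm[, c("city_id", "year", "month", "ambient", "month_start")],
              by = c("city_id", "year", "month")) %>%
    left_join(zall, by = c("city_id", "year", "month"))

  # --- monthly true exposures
  n_sm <- nrow(sm)
  eps <- rnorm(n_sm, 0, config$sigma_w)
  cov_raw <- covars[[config$gamma4_covariate]][sm$city_idx]
  n_clamped <- 0L
  if (config$mode == "regression_truth") {
    slope <- config$gamma1_true + g3[sm$city_idx] + config$gamma4_true * cov_raw
    x <- config$gamma0 + g1[sm$city_idx] + sm$g2 + slope * sm$z_gen +
      config$gamma2_true * sm$winter + eps
    n_clamped <- sum(x < 0)
    sm$x_month <- pmax(0, x)
    sm$x_amb_month <- sm$x_month
  } else {
    sm$x_amb_month <- sm$ratio * sm$ambient
    sm$x_month <- NA_real_ # total exposure assembled at day level below
  }

  # --- daily records
  day_sets <- lapply(seq_len(n_sm), function(i) sort(sample.int(28, D)))
  dl <- sm[rep(seq_len(n_sm), each = D),
           c("city_idx", "city_id", "subject_id", "year", "month",
             "ratio", "ambient", "z_gen", "x_month", "x_amb_month",
             "month_start")]
  dl$day <- unlist(day_sets)
  dl$date <- dl$month_start + (dl$day - 1L)

  aso4_cm <- pmax(0.2, 0.25 * dl$ambient) # ambient sulfate, constant in month
  if (config$mode == "regression_truth") {
    dl$personal_pm25 <- dl$x_month
    dl$ambient_so4 <- aso4_cm
    dl$personal_so4 <- pmax(0, dl$x_month / dl$z_gen * aso4_cm)
  } else {
    # personal exposure of ambient origin follows the day's ambient level
    aidx <- match(paste(dl$city_id, dl$date),
                  paste(mon$city_id, mon$date))
    a_day <- mon$a_day[aidx]
    nonamb <- pmax(0, rnorm(nrow(dl), config$nonambient_mean,
                            config$nonambient_sd))
    dl$personal_pm25 <- dl$ratio * a_day + nonamb
    dl$ambient_so4 <- aso4_cm
    dl$personal_so4 <- dl$ratio * aso4_cm
  }

  skey <- paste(subj$city_id, subj$subject_id)
  sidx <- match(paste(dl$city_id, dl$subject_id), skey)
  daily <- tibble(
    city_id = dl$city_id,
    subject_id = dl$subject_id,
    date = dl$date,
    age = subj$age[sidx],
    personal_pm25 = dl$personal_pm25,
    personal_so4 = dl$personal_so4,
    ambient_so4 = dl$ambient_so4,
    lat = subj$lat[sidx],
    lon = subj$lon[sidx],
    time_fraction_indoors = subj$time_fraction_indoors[sidx])

  # --- monthly outdoor-home model predictions
  model_pred <- sm %>%
    mutate(predicted_pm25 = pmax(0, .data$ambient +
                                   rnorm(n_sm, 0, config$model_pred_error_sd))) %>%
    select("city_id", "subject_id", "year", "month", "predicted_pm25") %>%
    as_tibble()

  truth <- c(
    unclass(config)[setdiff(names(unclass(config)), "distant_monitor_city")],
    list(distant_monitor_city = config$distant_monitor_city %||% NA_integer_,
         realized_mean_ratio = mean(subj$ratio),
         realized_mean_ambient = mean(cm$ambient),
         n_clamped_negative = n_clamped,
         implied_slope_ambient_origin = if (config$mode == "mechanistic")
           mean(subj$ratio) else config$gamma1_true))

  structure(list(daily = daily, monitors = monitors, model_pred = model_pred,
                 city_covariates = covars, truth = truth, config = config),
            class = "pm_panel")
}

#' @export
print.pm_panel <- function(x, ...) {
  cat("<pm_panel>", x$config$mode, "mode\n")
  cat(sprintf("  %d daily records, %d subjects, %d cities\n",
              nrow(x$daily),
              nrow(distinct(x$daily, .data$city_id, .data$subject_id)),
              n_distinct(x$daily$city_id)))
  cat(sprintf("  truth: gamma1 = %g (implied ambient-origin slope %.3f)\n",
              x$truth$gamma1_true, x$truth$implied_slope_ambient_origin))
  invisible(x)
}

days_in_month <- function(year, month) {
  nxt_y <- ifelse(month == 12L, year + 1L, year)
  nxt_m <- ifelse(month == 12L, 1L, month + 1L)
  as.integer(as.Date(sprintf("%d-%02d-01", nxt_y, nxt_m)) -
               as.Date(sprintf("%d-%02d-01", year, month)))
}

#' Write a simulated panel to the on-disk CSV contract
#'
#' Emits `daily.csv`, `monitors.csv`, `model_pred.csv`, `city_covariates.csv`
#' and a flat `truth.csv` (key/value) into `dir`. The files round-trip
#' losslessly through [read_panel_csv()], and a fixed seed yields
#' byte-identical files.
#'
#' @param panel A `pm_panel` from [simulate_panel()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the file paths written, invisibly.
#' @export
write_fixture <- function(panel, dir) {
  if (!inherits(panel, "pm_panel")) abort("`panel` must be a pm_panel object.")
  if (nrow(panel$daily) == 0) abort("Refusing to write an empty dataset.")
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create directory '%s'.", dir))
  }
  paths <- c(daily = file.path(dir, "daily.csv"),
             monitors = file.path(dir, "monitors.csv"),
             model_pred = file.path(dir, "model_pred.csv"),
             city_covariates = file.path(dir, "city_covariates.csv"),
             truth = file.path(dir, "truth.csv"))
  readr::write_csv(panel$daily, paths[["daily"]])
  readr::write_csv(panel$monitors, paths[["monitors"]])
  readr::write_csv(panel$model_pred, paths[["model_pred"]])
  readr::write_csv(panel$city_covariates, paths[["city_covariates"]])
  tr <- panel$truth
  flat <- vapply(tr, function(v) paste(format(v, digits = 17), collapse = ";"),
                 character(1))
  readr::write_csv(tibble(key = names(tr), value = unname(flat)),
                   paths[["truth"]])
  invisible(paths)
}
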