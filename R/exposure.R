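#' Personal PM2.5 of ambient origin by the sulfate tracer method
#'
#' Sulfate has negligible indoor sources, so the personal/ambient sulfate
#' ratio approximates the fraction of ambient PM2.5 that infiltrates indoors
#' and remains airborne. The personal exposure of ambient origin is that
#' ratio applied to the ambient PM2.5 concentration:
#' `personal_so4 / ambient_so4 * ambient_pm25`.
#'
#' A zero or missing ambient sulfate makes the ratio undefined; the result
#' is `NA` for those elements (with an informative message), never a
#' division error.
#'
#' @param personal_so4,ambient_so4 Personal and ambient sulfate (ug/m3),
#'   vectorized.
#' @param ambient_pm25 Ambient PM2.5 (ug/m3).
#' @return Numeric vector of ambient-origin personal PM2.5 (ug/m3).
#' @export
#' @examples
#' ambient_origin_tracer(2, 2, 15)    # ratio 1 returns ambient
#' ambient_origin_tracer(1, 2, 20)    # 10
ambient_origin_tracer <- function(personal_so4, ambient_so4, ambient_pm25) {
  if (any(personal_so4 < 0, na.rm = TRUE) ||
      any(ambient_so4 < 0, na.rm = TRUE) ||
      any(ambient_pm25 < 0, na.rm = TRUE)) {
    abort("Sulfate and PM2.5 concentrations must be non-negative.")
  }
  bad <- is.na(ambient_so4) | ambient_so4 == 0
  if (any(bad)) {
    inform(sprintf(
      "%d observation(s) with missing or zero ambient sulfate: tracer value set to NA.",
      sum(bad)))
  }
  out <- personal_so4 / ambient_so4 * ambient_pm25
  out[bad] <- NA_real_
  out
}

#' Time-weighted personal PM2.5 of ambient origin
#'
#' Variant used where personal sulfate is unavailable: the weighted average
#' of indoor PM2.5 of ambient origin (ambient times the home infiltration
#' efficiency) and ambient PM2.5, weighted by the fraction of time spent
#' indoors versus outdoors.
#'
#' @param ambient_pm25 Ambient PM2.5 (ug/m3).
#' @param infiltration_efficiency Home infiltration efficiency, in \[0, 1.5\].
#' @param time_fraction_indoors Fraction of time spent indoors, in \[0, 1\].
#' @return `time_fraction_indoors * infiltration_efficiency * ambient_pm25 +
#'   (1 - time_fraction_indoors) * ambient_pm25`.
#' @export
#' @examples
#' ambient_origin_timeweighted(20, 0.6, 0.5) # 16
ambient_origin_timeweighted <- function(ambient_pm25, infiltration_efficiency,
                                        time_fraction_indoors) {
  if (any(time_fraction_indoors < 0 | time_fraction_indoors > 1, na.rm = TRUE)) {
    abort("`time_fraction_indoors` must be in [0, 1].")
  }
  if (any(infiltration_efficiency < 0 | infiltration_efficiency > 1.5,
          na.rm = TRUE)) {
    abort("`infiltration_efficiency` must be in [0, 1.5].")
  }
  time_fraction_indoors * infiltration_efficiency * ambient_pm25 +
    (1 - time_fraction_indoors) * ambient_pm25
}

#' Assign heating-season labels to calendar months
#'
#' October--March is winter, April--September is summer.
#'
#' @param month_of_year Integer month(s) in 1..12.
#' @return Character vector, `"winter"` or `"summer"`.
#' @export
#' @examples
#' assign_season(c(10, 4, 12))
assign_season <- function(month_of_year) {
  if (any(is.na(month_of_year)) ||
      any(month_of_year < 1 | month_of_year > 12 |
            month_of_year != round(month_of_year))) {
    abort("`month_of_year` must contain integer months in 1..12.")
  }
  ifelse(month_of_year %in% c(10:12, 1:3), "winter", "summer")
}

#' Great-circle distance in miles
#'
#' Haversine distance on a sphere of radius 3958.8 miles (via
#' [geosphere::distHaversine()]), vectorized over point pairs.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in miles.
#' @export
haversine_mi <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 3958.8)
}

check_coords <- function(lat, lon) {
  if (any(abs(lat) > 90, na.rm = TRUE) || any(abs(lon) > 180, na.rm = TRUE)) {
    abort("Invalid coordinates: |lat| must be <= 90 and |lon| <= 180.")
  }
  if (any(is.na(lat) | is.na(lon))) {
    abort("Coordinates must not be missing.")
  }
  invisible(TRUE)
}

#' Nearest air-quality monitor within a distance cap
#'
#' Returns the monitor minimizing the great-circle distance to a residence,
#' or `NA` when even the closest monitor exceeds `max_distance_mi` (30 miles
#' by default, the usual monitor-matching rule in exposure assessment).
#' Exact ties are broken by `monitor_id` order for determinism.
#'
#' @param lat,lon Residence coordinates (decimal degrees).
#' @param monitors Data frame with columns `monitor_id`, `lat`, `lon`
#'   (repeated daily rows are allowed; locations are deduplicated).
#' @param max_distance_mi Maximum allowed monitor-residence distance.
#' @return A one-row tibble with `monitor_id` (NA if none qualifies) and
#'   `distance_mi`.
#' @export
nearest_monitor <- function(lat, lon, monitors, max_distance_mi = 30) {
  rk <- rank_monitors(lat, lon, monitors)
  if (rk$distance_mi[1] > max_distance_mi) {
    return(tibble(monitor_id = NA_character_, distance_mi = rk$distance_mi[1]))
  }
  rk[1, ]
}

# all monitors ordered by (distance, monitor_id); used for day-level fallback
rank_monitors <- function(lat, lon, monitors) {
  check_columns(monitors, c("monitor_id", "lat", "lon"), "monitors")
  loc <- distinct(monitors, .data$monitor_id, .data$lat, .data$lon)
  if (nrow(loc) == 0) abort("At least one monitor must be supplied.")
  d <- haversine_mi(lat, lon, loc$lat, loc$lon)
  tibble(monitor_id = loc$monitor_id, distance_mi = d) %>%
    arrange(.data$distance_mi, .data$monitor_id)
}

#' Monthly average of a monitor series
#'
#' Computes the monthly mean ambient concentration either from all available
#' days in the month (`"all_days"`, as done when monitor data are richer than
#' the personal sampling) or from the personal sampling days only
#' (`"matched_days"`, the temporally matched sensitivity variant).
#'
#' @param series Data frame with columns `date` and `ambient_pm25` for one
#'   monitor.
#' @param year,month Calendar month to average.
#' @param mode `"all_days"` or `"matched_days"`.
#' @param personal_days Date vector of personal sampling days (required for
#'   `"matched_days"`).
#' @return The mean concentration, or `NA` when no qualifying day has data.
#' @export
monthly_monitor_average <- function(series, year, month,
                                    mode = c("all_days", "matched_days"),
                                    personal_days = NULL) {
  mode <- match.arg(mode)
  check_columns(series, c("date", "ambient_pm25"), "series")
  in_month <- !is.na(series$date) &
    as.integer(format(series$date, "%Y")) == year &
    as.integer(format(series$date, "%m")) == month
  vals <- series$ambient_pm25[in_month]
  dts <- series$date[in_month]
  if (mode == "matched_days") {
    if (is.null(personal_days)) {
      abort("`personal_days` is required for matched_days mode.")
    }
    vals <- vals[dts %in% personal_days]
  }
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}

check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Build the monthly analysis table from daily records
#'
#' Turns daily personal measurements into the person-month analysis units of
#' the calibration models: excludes minors, averages personal PM2.5 within
#' subject-month, applies the sulfate tracer to obtain personal PM2.5 of
#' ambient origin, attaches the two surrogate exposures (nearest-monitor
#' monthly average and outdoor-home model prediction) and the season label.
#'
#' The tracer is applied to monthly means by default (ratio of the monthly
#' mean personal to ambient sulfate, times the monitor mean over the personal
#' sampling days); `tracer = "mean_of_daily"` instead averages the daily
#' tracer values. The nearest-monitor surrogate uses all days in the month
#' (`monitor_mode = "all_days"`) or only the personal sampling days
#' (`"matched_days"`); in either case, days without data at the assigned
#' monitor fall back to the nearest monitor with data that day.
#'
#' @param daily Daily records: `city_id`, `subject_id`, `date`, `age`,
#'   `personal_pm25`, `personal_so4`, `ambient_so4`, `lat`, `lon`,
#'   `time_fraction_indoors`.
#' @param monitors Monitor series: `monitor_id`, `lat`, `lon`, `date`,
#'   `ambient_pm25`.
#' @param model_pred Optional monthly predictions: `city_id`, `subject_id`,
#'   `year`, `month`, `predicted_pm25`.
#' @param min_days_per_month Minimum personal sampling days required to form
#'   a monthly average (default 1).
#' @param max_monitor_distance_mi Monitor-matching distance cap (miles).
#' @param monitor_mode `"all_days"` or `"matched_days"`.
#' @param tracer `"ratio_of_means"` or `"mean_of_daily"`.
#' @param min_age Minimum eligible age (years); younger subjects are dropped.
#' @param verbose Emit person-month retention counts as messages.
#' @return A tibble with one row per person-month: `city_id`, `subject_id`,
#'   `month_index`, `year`, `month`, `season`, `age`, `x_ambient_origin`,
#'   `x_total_personal`, `z_monitor`, `z_model_pred`, `n_personal_days`,
#'   `monitor_id`, `monitor_distance_mi`.
#' @export
build_analysis_table <- function(daily, monitors, model_pred = NULL,
                                 min_days_per_month = 1,
                                 max_monitor_distance_mi = 30,
                                 monitor_mode = c("all_days", "matched_days"),
                                 tracer = c("ratio_of_means", "mean_of_daily"),
                                 min_age = 18,
                                 verbose = TRUE) {
  monitor_mode <- match.arg(monitor_mode)
  tracer <- match.arg(tracer)
  check_columns(daily, c("city_id", "subject_id", "date", "age",
                         "personal_pm25", "personal_so4", "ambient_so4",
                         "lat", "lon"), "daily")
  check_columns(monitors, c("monitor_id", "lat", "lon", "date",
                            "ambient_pm25"), "monitors")
  if (!is.null(model_pred)) {
    check_columns(model_pred, c("city_id", "subject_id", "year", "month",
                                "predicted_pm25"), "model_pred")
  }

  n_minors <- nrow(distinct(filter(daily, .data$age < min_age),
                            .data$city_id, .data$subject_id))
  daily <- filter(daily, .data$age >= min_age)
  if (nrow(daily) == 0) abort("No eligible subjects after the age filter.")

  # one residence (first record) and one assigned monitor per subject
  skey <- paste(daily$city_id, daily$subject_id, sep = "\r")
  sfirst <- !duplicated(skey)
  subj <- tibble(city_id = daily$city_id[sfirst],
                 subject_id = daily$subject_id[sfirst],
                 lat = daily$lat[sfirst], lon = daily$lon[sfirst],
                 age = daily$age[sfirst])
  loc <- distinct(monitors, .data$monitor_id, .data$lat, .data$lon)
  if (nrow(loc) == 0) abort("At least one monitor must be supplied.")
  loc <- arrange(loc, .data$monitor_id) # lexicographic tie-break
  dmat <- vapply(seq_len(nrow(loc)),
                 function(j) haversine_mi(subj$lat, subj$lon,
                                          loc$lat[j], loc$lon[j]),
                 numeric(nrow(subj)))
  dmat <- matrix(dmat, nrow = nrow(subj))
  jmin <- max.col(-dmat, ties.method = "first")
  dmin <- dmat[cbind(seq_len(nrow(subj)), jmin)]
  subj$monitor_id <- ifelse(dmin <= max_monitor_distance_mi,
                            loc$monitor_id[jmin], NA_character_)
  subj$monitor_distance_mi <- dmin

  dd <- daily
  sidx <- match(skey, paste(subj$city_id, subj$subject_id, sep = "\r"))
  dd$monitor_id <- subj$monitor_id[sidx]
  dd$monitor_distance_mi <- subj$monitor_distance_mi[sidx]
  lt <- as.POSIXlt(dd$date)
  dd$year <- lt$year + 1900L
  dd$month <- lt$mon + 1L

  # monitor value on each personal sampling day, with nearest-with-data fallback
  dd <- dd %>%
    left_join(select(monitors, "monitor_id", "date",
                     mon_pm_day = "ambient_pm25"),
              by = c("monitor_id", "date"))
  need_fb <- which(is.na(dd$mon_pm_day) & !is.na(dd$monitor_id))
  if (length(need_fb)) {
    have <- monitors[!is.na(monitors$ambient_pm25), ]
    for (i in need_fb) {
      cand <- have[have$date == dd$date[i], ]
      if (nrow(cand) == 0) next
      rk <- rank_monitors(dd$lat[i], dd$lon[i], cand)
      rk <- rk[rk$distance_mi <= max_monitor_distance_mi, ]
      if (nrow(rk) == 0) next
      dd$mon_pm_day[i] <-
        cand$ambient_pm25[match(rk$monitor_id[1], cand$monitor_id)]
    }
  }

  # person-month aggregation (rowsum-based for speed at simulation scale)
  mkey <- paste(dd$city_id, dd$subject_id, dd$year, dd$month, sep = "\r")
  grp <- match(mkey, unique(mkey))
  gmean <- function(v) {
    ok <- !is.na(v)
    s <- unname(rowsum(ifelse(ok, v, 0), grp)[, 1])
    k <- unname(rowsum(as.numeric(ok), grp)[, 1])
    ifelse(k > 0, s / k, NA_real_)
  }
  mfirst <- !duplicated(grp)
  daily_tracer <- dd$personal_so4 / ifelse(
    is.na(dd$ambient_so4) | dd$ambient_so4 == 0, NA_real_, dd$ambient_so4) *
    dd$mon_pm_day
  monthly <- tibble(
    city_id = dd$city_id[mfirst],
    subject_id = dd$subject_id[mfirst],
    year = dd$year[mfirst],
    month = dd$month[mfirst],
    n_personal_days = tabulate(grp),
    age = dd$age[mfirst],
    monitor_id = dd$monitor_id[mfirst],
    monitor_distance_mi = dd$monitor_distance_mi[mfirst],
    x_total_personal = gmean(dd$personal_pm25),
    pso4_m = gmean(dd$personal_so4),
    aso4_m = gmean(dd$ambient_so4),
    mon_matched = gmean(dd$mon_pm_day),
    x_amb_daily = gmean(daily_tracer)) %>%
    filter(.data$n_personal_days >= min_days_per_month)

  monthly$x_ambient_origin <- if (tracer == "ratio_of_means") {
    suppressMessages(ambient_origin_tracer(monthly$pso4_m, monthly$aso4_m,
                                           monthly$mon_matched))
  } else {
    monthly$x_amb_daily
  }

  # nearest-monitor surrogate: all-days monthly mean or matched-days mean
  if (monitor_mode == "all_days") {
    mlt <- as.POSIXlt(monitors$date)
    mon_month <- monitors %>%
      mutate(year = mlt$year + 1900L, month = mlt$mon + 1L) %>%
      group_by(.data$monitor_id, .data$year, .data$month) %>%
      summarise(z_monitor = mean_or_na(.data$ambient_pm25), .groups = "drop")
    monthly <- left_join(monthly, mon_month,
                         by = c("monitor_id", "year", "month"))
  } else {
    monthly$z_monitor <- monthly$mon_matched
  }

  if (!is.null(model_pred)) {
    monthly <- left_join(
      monthly,
      select(model_pred, "city_id", "subject_id", "year", "month",
             z_model_pred = "predicted_pm25"),
      by = c("city_id", "subject_id", "year", "month"))
  } else {
    monthly$z_model_pred <- NA_real_
  }

  out <- monthly %>%
    mutate(season = assign_season(.data$month)) %>%
    group_by(.data$city_id, .data$subject_id) %>%
    arrange(.data$year, .data$month, .by_group = TRUE) %>%
    mutate(month_index = row_number()) %>%
    ungroup() %>%
    select("city_id", "subject_id", "month_index", "year", "month", "season",
           "age", "x_ambient_origin", "x_total_personal", "z_monitor",
           "z_model_pred", "n_personal_days", "monitor_id",
           "monitor_distance_mi") %>%
    arrange(.data$city_id, .data$subject_id, .data$month_index)

  if (verbose) {
    inform(sprintf(
      paste0("Analysis table: %d person-months from %d subjects in %d cities",
             " (%d under-%s subject(s) excluded; %d person-months lack the",
             " tracer exposure)."),
      nrow(out), nrow(distinct(out, .data$city_id, .data$subject_id)),
      n_distinct(out$city_id), n_minors, format(min_age),
      sum(is.na(out$x_ambient_origin))))
  }
  out
}

mean_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  mean(x)
}
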