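#' Configure an end-to-end calibration run
#'
#' Assembles the options of [run_calibration()]: the data source (a
#' [sim_config()] in synthetic mode or CSV paths in files mode), the 2x2
#' analysis grid of true exposures by surrogates, the sensitivity switches,
#' and the heterogeneity / cross-validation settings.
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param sim A [sim_config()] (synthetic mode).
#' @param paths Named list/character of file paths `daily`, `monitors`,
#'   `model_pred`, `city_covariates` (files mode).
#' @param true_exposures,surrogates Grid axes; defaults give all four cells.
#' @param matched_days Build the nearest-monitor surrogate from personal
#'   sampling days only (temporal-matching sensitivity analysis).
#' @param restrict_to_tracer_subset Re-run the total-personal analyses on
#'   exactly the person-months for which the tracer (ambient-origin)
#'   exposure exists.
#' @param subgroup_flags Optional names of binary subject-level columns for
#'   effect-modification sensitivity analyses.
#' @param candidates City covariates offered to stepwise selection when
#'   heterogeneity is found.
#' @param alpha Significance level used throughout.
#' @param min_days_per_month Minimum sampling days per person-month.
#' @param seed Integer seed governing all randomness of the run.
#' @param out_dir Optional directory for the report bundle (summary and
#'   per-city CSVs, run log JSON, forest plots).
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"),
                       sim = sim_config(),
                       paths = NULL,
                       true_exposures = c("ambient_origin", "total_personal"),
                       surrogates = c("monitor", "model_pred"),
                       matched_days = FALSE,
                       restrict_to_tracer_subset = FALSE,
                       subgroup_flags = NULL,
                       candidates = c("vehicles_per_unit",
                                      "heating_degree_days",
                                      "residents_per_unit"),
                       alpha = 0.05,
                       min_days_per_month = 1,
                       seed = 1L,
                       out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "files") {
    need <- c("daily", "monitors", "model_pred", "city_covariates")
    if (is.null(paths) || !all(need %in% names(paths))) {
      abort(sprintf("files mode requires `paths` naming: %s.",
                    paste(need, collapse = ", ")))
    }
  }
  true_exposures <- match.arg(true_exposures, several.ok = TRUE)
  surrogates <- match.arg(surrogates, several.ok = TRUE)
  structure(list(mode = mode, sim = sim, paths = paths,
                 true_exposures = true_exposures, surrogates = surrogates,
                 matched_days = matched_days,
                 restrict_to_tracer_subset = restrict_to_tracer_subset,
                 subgroup_flags = subgroup_flags,
                 candidates = candidates, alpha = alpha,
                 min_days_per_month = min_days_per_month,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Reads a human-editable YAML file whose keys mirror the arguments of
#' [run_config()] (a `sim:` block maps onto [sim_config()]).
#'
#' @param path Path to the YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file '%s' not found.", path))
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s) in '%s': %s.",
                  path, paste(unknown, collapse = ", ")))
  }
  do.call(run_config, y)
}

# ---- CSV contract readers ---------------------------------------------------

read_checked_csv <- function(path, spec, what) {
  if (!file.exists(path)) abort(sprintf("File '%s' not found.", path))
  df <- suppressWarnings(
    readr::read_csv(path, col_types = spec, show_col_types = FALSE))
  miss <- setdiff(names(spec$cols), names(df))
  if (length(miss)) {
    abort(sprintf("File '%s' (%s) is missing column(s): %s.",
                  path, what, paste(miss, collapse = ", ")))
  }
  pr <- readr::problems(df)
  if (nrow(pr) > 0) {
    abort(sprintf("File '%s', column '%s', line %d: expected %s, got '%s'.",
                  path, names(df)[pr$col[1]] %||% pr$col[1], pr$row[1],
                  pr$expected[1], pr$actual[1]))
  }
  df
}

#' Read the on-disk CSV contract of a panel dataset
#'
#' Reads and schema-checks the four CSV files written by [write_fixture()]
#' (or assembled from real studies in the same layout). Malformed values are
#' reported with file, column, and row.
#'
#' @param paths Named list/character with elements `daily`, `monitors`,
#'   `model_pred`, `city_covariates`.
#' @return A list with tibbles `daily`, `monitors`, `model_pred`,
#'   `city_covariates`.
#' @export
read_panel_csv <- function(paths) {
  daily <- read_checked_csv(paths[["daily"]], readr::cols(
    city_id = readr::col_character(), subject_id = readr::col_character(),
    date = readr::col_date(), age = readr::col_double(),
    personal_pm25 = readr::col_double(), personal_so4 = readr::col_double(),
    ambient_so4 = readr::col_double(), lat = readr::col_double(),
    lon = readr::col_double(),
    time_fraction_indoors = readr::col_double()), "daily records")
  monitors <- read_checked_csv(paths[["monitors"]], readr::cols(
    monitor_id = readr::col_character(), lat = readr::col_double(),
    lon = readr::col_double(), date = readr::col_date(),
    ambient_pm25 = readr::col_double()), "monitor series")
  model_pred <- read_checked_csv(paths[["model_pred"]], readr::cols(
    city_id = readr::col_character(), subject_id = readr::col_character(),
    year = readr::col_integer(), month = readr::col_integer(),
    predicted_pm25 = readr::col_double()), "model predictions")
  covars <- read_checked_csv(paths[["city_covariates"]], readr::cols(
    city_id = readr::col_character(), .default = readr::col_double()),
    "city covariates")
  list(daily = daily, monitors = monitors, model_pred = model_pred,
       city_covariates = covars)
}

# ---- orchestration ----------------------------------------------------------

#' Run the full calibration analysis
#'
#' Executes the analysis sequence end to end: build the monthly analysis
#' table, then for each cell of the true-exposure-by-surrogate grid fit the
#' pooled calibration model, test the coefficient against 1, assess seasonal
#' effect modification, and test between-city heterogeneity. Where
#' heterogeneity is significant the run continues with stepwise city
#' covariate selection, per-city fits, and leave-one-city-out
#' cross-validation; where it is not, the model without the city random
#' slope is refitted and reported as the final coefficient.
#'
#' @param config A [run_config()].
#' @return A list of class `calib_run`: `summary` (one row per grid cell
#'   with the calibration coefficient, CI, p-values and sample sizes),
#'   `cells` (per-cell detail: fits, heterogeneity, stepwise, LOOCV,
#'   per-city coefficients, or the failed stage), `table` (the analysis
#'   table), `truth` (synthetic mode only), and `log`.
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config(sim = sim_config(n_cities = 4, subjects_per_city = 8,
#'                                    months_per_subject = 4, seed = 3),
#'                   seed = 3)
#' res <- run_calibration(cfg)
#' res$summary
#' }
run_calibration <- function(config) {
  if (!inherits(config, "run_config")) {
    abort("`config` must be created with run_config() or read_run_config().")
  }
  set.seed(config$seed)

  if (config$mode == "synthetic") {
    panel <- simulate_panel(config$sim)
    daily <- panel$daily; monitors <- panel$monitors
    model_pred <- panel$model_pred; covars <- panel$city_covariates
    truth <- panel$truth
  } else {
    inp <- read_panel_csv(config$paths)
    daily <- inp$daily; monitors <- inp$monitors
    model_pred <- inp$model_pred; covars <- inp$city_covariates
    truth <- NULL
  }

  tab <- build_analysis_table(
    daily, monitors, model_pred,
    min_days_per_month = config$min_days_per_month,
    monitor_mode = if (config$matched_days) "matched_days" else "all_days",
    verbose = FALSE)

  grid <- tidyr::expand_grid(true_exposure = config$true_exposures,
                             surrogate = config$surrogates)
  cells <- purrr::pmap(grid, function(true_exposure, surrogate) {
    run_cell(tab, covars, true_exposure, surrogate, config)
  })
  names(cells) <- paste(grid$true_exposure, grid$surrogate, sep = ".")

  summary <- purrr::map_dfr(cells, "summary")
  log <- list(seed = config$seed,
              config_hash = rlang::hash(config),
              package_version = as.character(utils::packageVersion("pmcalib")),
              n_person_months = nrow(tab),
              n_subjects = nrow(distinct(tab, .data$city_id, .data$subject_id)),
              n_cities = n_distinct(tab$city_id),
              converged = purrr::map_lgl(cells, function(cl)
                isTRUE(cl$fit_model1$converged)),
              failed_stage = purrr::map_chr(cells, function(cl)
                cl$failed_stage %||% NA_character_))

  res <- structure(list(summary = summary, cells = cells, table = tab,
                        truth = truth, log = log, config = config),
                   class = "calib_run")
  if (!is.null(config$out_dir)) write_run_bundle(res, config$out_dir)
  res
}

run_cell <- function(tab, covars, true_exposure, surrogate, config) {
  xcol <- switch(true_exposure, ambient_origin = "x_ambient_origin",
                 total_personal = "x_total_personal")
  zcol <- switch(surrogate, monitor = "z_monitor", model_pred = "z_model_pred")
  d <- tab[!is.na(tab[[xcol]]) & !is.na(tab[[zcol]]), ]
  if (config$restrict_to_tracer_subset && true_exposure == "total_personal") {
    d <- d[!is.na(d$x_ambient_origin), ]
  }
  cell <- list(true_exposure = true_exposure, surrogate = surrogate,
               failed_stage = NULL)
  fail_row <- function(stage, e) {
    cell$failed_stage <<- stage
    cell$error <<- conditionMessage(e)
    NULL
  }

  season <- tryCatch(
    suppressWarnings(season_modification(d, true_exposure, surrogate,
                                         alpha = config$alpha)),
    error = function(e) fail_row("season_modification", e))
  if (is.null(season)) {
    cell$summary <- tibble(true_exposure = true_exposure,
                           surrogate = surrogate, n_person_months = nrow(d),
                           gamma1_hat = NA_real_)
    return(cell)
  }
  cell$fit_model1 <- season$fit_main
  cell$season <- season

  het <- tryCatch(
    suppressWarnings(heterogeneity_test(d, true_exposure, surrogate)),
    error = function(e) fail_row("heterogeneity_test", e))
  cell$heterogeneity <- het

  final <- season$report
  if (!is.null(het) && het$p_value < config$alpha) {
    cell$city_fits <- tryCatch(
      suppressWarnings(city_specific_fits(d, true_exposure, surrogate,
                                          alpha = config$alpha)),
      error = function(e) fail_row("city_specific_fits", e))
    if (length(config$candidates) && n_distinct(d$city_id) >= 3) {
      cell$stepwise <- tryCatch(
        suppressWarnings(stepwise_city_covariates(
          d, covars, config$candidates, true_exposure, surrogate,
          alpha = config$alpha)),
        error = function(e) fail_row("stepwise_city_covariates", e))
      cell$loocv <- tryCatch(
        suppressWarnings(loocv_city_coefficients(
          d, covars, config$candidates, true_exposure, surrogate,
          alpha = config$alpha)),
        error = function(e) fail_row("loocv_city_coefficients", e))
    }
  } else if (!is.null(het)) {
    # no heterogeneity detected: report the model without the city random
    # slope as the final coefficient
    m2 <- tryCatch(
      suppressWarnings(fit_calibration(d, "model2", true_exposure, surrogate)),
      error = function(e) fail_row("model2_refit", e))
    if (!is.null(m2)) {
      cell$fit_model2 <- m2
      final <- calibration_report(m2, alpha = config$alpha)
    }
  }

  cell$summary <- tibble(
    true_exposure = true_exposure, surrogate = surrogate,
    n_person_months = nrow(d),
    n_subjects = nrow(distinct(d, .data$city_id, .data$subject_id)),
    n_cities = n_distinct(d$city_id),
    gamma1_hat = season$report$gamma1_hat,
    ci_low = season$report$ci_low, ci_high = season$report$ci_high,
    p_value_1 = season$report$p_value_1,
    season_interaction_p = season$interaction_p,
    het_p = if (is.null(het)) NA_real_ else het$p_value,
    het_boundary = if (is.null(het)) NA else het$boundary,
    final_model = final$model,
    final_gamma1 = final$gamma1_hat,
    final_ci_low = final$ci_low, final_ci_high = final$ci_high)
  cell
}

write_run_bundle <- function(res, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create output directory '%s'.", out_dir))
  }
  readr::write_csv(res$summary, file.path(out_dir, "summary.csv"))
  for (nm in names(res$cells)) {
    cf <- res$cells[[nm]]$city_fits
    if (!is.null(cf)) {
      readr::write_csv(as_tibble(cf),
                       file.path(out_dir, paste0("per_city_", nm, ".csv")))
      p <- plot_city_forest(cf)
      ggplot2::ggsave(file.path(out_dir, paste0("forest_", nm, ".png")),
                      p, width = 6, height = 4, dpi = 150)
    }
  }
  jsonlite::write_json(res$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.calib_run <- function(x, ...) {
  cat("<calib_run>", x$log$n_person_months, "person-months,",
      x$log$n_cities, "cities (seed", paste0(x$log$seed, ")\n"))
  print(select(x$summary, "true_exposure", "surrogate", "gamma1_hat",
               "ci_low", "ci_high", "het_p", "final_model", "final_gamma1"))
  invisible(x)
}
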