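# Independent oracles and small fixture builders used across the suite.

# spherical-law-of-cosines great-circle distance (miles); independent of the
# haversine implementation in the package
slc_mi <- function(lat1, lon1, lat2, lon2, r = 3958.8) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  arg <- sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl)
  r * acos(pmin(1, pmax(-1, arg)))
}

# closed-form GLS fixed effects for a given dense covariance
gls_beta <- function(X, y, V) {
  Vi <- solve(V)
  drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y))
}

# dense-matrix restricted log-likelihood at fixed variance components
dense_reml_loglik <- function(X, y, V) {
  n <- nrow(X); p <- ncol(X)
  Vi <- solve(V)
  beta <- gls_beta(X, y, V)
  r <- y - X %*% beta
  -0.5 * ((n - p) * log(2 * pi) +
            as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(t(X) %*% Vi %*% X)$modulus) +
            drop(t(r) %*% Vi %*% r))
}

# balanced toy analysis table (deterministic given the seed)
toy_table <- function(n_cities = 2, n_subjects = 2, n_months = 4, seed = 1,
                      gamma1 = 0.6, sigma_subject = 1, sigma_w = 2) {
  set.seed(seed)
  d <- tidyr::expand_grid(city_id = sprintf("c%02d", seq_len(n_cities)),
                          subject_id = sprintf("s%02d", seq_len(n_subjects)),
                          month_index = seq_len(n_months))
  d$year <- 2000L
  d$month <- rep_len(c(1L, 4L, 7L, 10L), nrow(d))
  d$season <- assign_season(d$month)
  d$z_monitor <- rnorm(nrow(d), 15, 5)
  d$z_model_pred <- d$z_monitor
  re_subj <- rnorm(n_cities * n_subjects, 0, sigma_subject)
  sid <- as.integer(factor(paste(d$city_id, d$subject_id)))
  d$x_total_personal <- 3 + gamma1 * d$z_monitor - 1 * (d$season == "winter") +
    re_subj[sid] + rnorm(nrow(d), 0, sigma_w)
  d$x_ambient_origin <- d$x_total_personal
  d$n_personal_days <- 5L
  d$age <- 60
  d
}

# small simulated panel + analysis table in one call
quick_panel_table <- function(..., seed = 1) {
  panel <- simulate_panel(sim_config(..., seed = seed))
  tab <- build_analysis_table(panel$daily, panel$monitors, panel$model_pred,
                              verbose = FALSE)
  list(panel = panel, tab = tab)
}
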