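#' Simulation configuration for synthetic hourly data
#'
#' Defines the generative model used for end-to-end testing: daily PM2.5
#' follows the seasonal linear model exactly — intercept, additive calendar
#' month effects, a linear trend in the day index, linear effects of five
#' meteorological covariates, and i.i.d. Gaussian noise — and hourly values
#' are the daily mean plus mean-zero within-day variation, so the 24-hour
#' average recovers the daily value. Covariates follow annual sinusoids
#' plus noise, with defaults calibrated so their simulated ranges resemble
#' an inland Iranian city. A small fraction of zero/negative sentinel
#' values is injected into the pollutant series to exercise the cleaning
#' rule, and hours are deleted independently to emulate monitor downtime.
#'
#' @param seed Integer RNG seed; the whole simulation is a deterministic
#'   function of the configuration.
#' @param start,end First and last simulated day (`Date` or parseable
#'   string).
#' @param beta Named list of true coefficients: `intercept`; `trend`
#'   (ug/m3 per day); one slope per covariate (ug/m3 per covariate unit);
#'   `months`, a named vector of month effects relative to the first
#'   simulated month.
#' @param sigma Daily noise SD (ug/m3).
#' @param within_day_sd SD of the mean-zero within-day variation (ug/m3).
#' @param covariates Named list of generator parameter lists
#'   `list(mean=, amplitude=, phase=, sd=)`; the daily value is
#'   `mean + amplitude * sin(2*pi*(doy - phase)/365) + N(0, sd)`.
#' @param missing_prob Per-hour probability that a record is absent.
#' @param sentinel_prob Per-hour probability that a pollutant record is
#'   replaced by a zero/negative sentinel.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       start = "2019-01-01", end = "2019-12-31",
                       beta = list(
                         intercept = 25,
                         trend = 0.01,
                         tmpf = -0.30, relh = 0.05, drct = 0.10,
                         sknt = -0.10, p01i = 0.01,
                         months = c(
                           february = 2, march = -1, april = -3, may = -2,
                           june = 4, july = 6, august = 3, september = 1,
                           october = 2, november = 3, december = 5
                         )
                       ),
                       sigma = 5,
                       within_day_sd = 3,
                       covariates = list(
                         tmpf = list(mean = 15, amplitude = 12, phase = 105, sd = 3),
                         relh = list(mean = 64, amplitude = 10, phase = 288, sd = 5),
                         drct = list(mean = 39, amplitude = 5, phase = 0, sd = 4),
                         sknt = list(mean = 47, amplitude = 10, phase = 50, sd = 6),
                         p01i = list(mean = 170, amplitude = 50, phase = 200, sd = 20)
                       ),
                       missing_prob = 0.02,
                       sentinel_prob = 0.005) {
  start <- as.Date(start)
  end <- as.Date(end)
  if (is.na(start) || is.na(end) || end < start) {
    stop("date range must be non-empty")
  }
  stopifnot(
    sigma >= 0, within_day_sd >= 0,
    missing_prob >= 0, missing_prob < 1,
    sentinel_prob >= 0, sentinel_prob < 1
  )
  cov_slopes <- setdiff(names(beta), c("intercept", "trend", "months"))
  if (!setequal(cov_slopes, names(covariates))) {
    stop("beta must contain exactly one slope per covariate generator")
  }
  structure(
    list(
      seed = as.integer(seed), start = start, end = end, beta = beta,
      sigma = sigma, within_day_sd = within_day_sd,
      covariates = covariates,
      missing_prob = missing_prob, sentinel_prob = sentinel_prob
    ),
    class = "sim_config"
  )
}

.sim_daily_covariates <- function(config, dates) {
  doy <- as.integer(format(dates, "%j"))
  out <- list()
  for (nm in names(config$covariates)) {
    g <- config$covariates[[nm]]
    out[[nm]] <- g$mean + g$amplitude * sin(2 * pi * (doy - g$phase) / 365) +
      stats::rnorm(length(dates), 0, g$sd)
  }
  out
}

.sim_hourly_from_daily <- function(dates, daily_values, within_day_sd,
                                   missing_prob, variable_name) {
  n_days <- length(dates)
  ts <- as.POSIXct(rep(dates, each = 24), tz = "UTC") +
    rep(0:23, times = n_days) * 3600
  dev <- if (within_day_sd > 0) {
    d <- matrix(stats::rnorm(24 * n_days, 0, within_day_sd), nrow = 24)
    as.vector(sweep(d, 2, colMeans(d))) # centre per day: 24-h mean is exact
  } else {
    numeric(24 * n_days)
  }
  vals <- rep(daily_values, each = 24) + dev
  keep <- stats::runif(length(vals)) >= missing_prob
  hourly_series(ts[keep], vals[keep], variable_name, n_dropped = 0L)
}

#' Simulate hourly PM2.5 and meteorology with known truth
#'
#' Draws one realisation of the generative model in [sim_config] and
#' returns raw hourly series (pollutant sentinels included) together with
#' a truth record holding every quantity needed to score downstream
#' recovery: the true coefficient vector, noise SD, the injected sentinel
#' count and the noise-free and realised daily tables.
#'
#' Pollutant hourly values are floored at 0.1 ug/m3 (a detection-limit
#' floor) before sentinel injection, so the only non-positive records in
#' the output are the injected sentinels and the cleaning-rule drop count
#' is exactly the sentinel count.
#'
#' @param config A [sim_config].
#' @return List with components `pm25` ([hourly_series], raw), `met`
#'   (named list of [hourly_series]), and `truth` (list: `beta` named
#'   vector, `sigma`, `n_sentinels`, `reference_month`, `daily` data
#'   frame).
#' @export
simulate_hourly <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dates <- seq(config$start, config$end, by = "day")
  n <- length(dates)
  trend <- as.numeric(dates - dates[1L])
  month_idx <- as.integer(format(dates, "%m"))
  reference_month <- month_idx[1L]

  covs <- .sim_daily_covariates(config, dates)

  month_names <- tolower(month.name[month_idx])
  month_effect <- ifelse(
    month_idx == reference_month, 0,
    unname(config$beta$months[month_names])
  )
  month_effect[is.na(month_effect)] <- 0

  mu <- config$beta$intercept + month_effect + config$beta$trend * trend
  for (nm in names(covs)) mu <- mu + config$beta[[nm]] * covs[[nm]]
  y_daily <- mu + stats::rnorm(n, 0, config$sigma)

  pm25 <- .sim_hourly_from_daily(
    dates, y_daily, config$within_day_sd, config$missing_prob, "pm25"
  )
  pm25$values <- pmax(pm25$values, 0.1) # detection-limit floor
  n_sent <- 0L
  if (config$sentinel_prob > 0) {
    sent <- stats::runif(length(pm25$values)) < config$sentinel_prob
    if (any(sent)) {
      pm25$values[sent] <- sample(c(0, -1, -5), sum(sent), replace = TRUE)
      n_sent <- sum(sent)
    }
  }

  met <- list()
  for (nm in names(covs)) {
    met[[nm]] <- .sim_hourly_from_daily(
      dates, covs[[nm]], config$within_day_sd, config$missing_prob, nm
    )
  }

  beta_vec <- c(
    "(Intercept)" = config$beta$intercept,
    unlist(config$beta[names(config$covariates)]),
    trend = config$beta$trend,
    config$beta$months
  )

  daily <- data.frame(date = dates, trend = trend, mu = mu, pm25 = y_daily)
  for (nm in names(covs)) daily[[nm]] <- covs[[nm]]

  list(
    pm25 = pm25, met = met,
    truth = list(
      beta = beta_vec, sigma = config$sigma, n_sentinels = n_sent,
      reference_month = reference_month, daily = daily, config = config
    )
  )
}

#' Write a simulated data set in the ingest CSV dialect
#'
#' @param sim Output of [simulate_hourly].
#' @param dir Output directory (created if needed); one CSV per series
#'   plus `truth.json`.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_hourly(sim$pm25, file.path(dir, "pm25.csv"))
  for (nm in names(sim$met)) {
    write_hourly(sim$met[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  truth <- sim$truth
  truth$daily <- NULL
  truth$config <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "pmhia")
  if (path == "") stop("bundled data file not found: ", file)
  path
}

#' Bundled endpoint and population fixtures
#'
#' Returns the baseline-incidence table for the seven Iranian cities
#' (Arak, Esfahan, Ahvaz, Tabriz, Shiraz, Karaj, Mashhad; six long-term
#' mortality endpoints each, WHO AirQ+ baseline incidences per 100,000)
#' together with a set of at-risk population counts. The population counts
#' are synthetic round values chosen at plausible city scale — the
#' underlying assessment does not publish its at-risk counts — and are
#' suitable for exercising the pipeline, not for substantive estimates.
#'
#' The all-cause endpoint uses a log-linear relative risk of 1.062
#' (95% CI 1.04-1.083) per 10 ug/m3; the cause-specific endpoints are
#' conventionally assessed with integrated exposure-response curves whose
#' parameters must be supplied by the user (see [crf_ier]).
#'
#' @return List with `endpoints` (data frame `city, endpoint, age_group,
#'   baseline_incidence, crf`), `populations` (data frame, synthetic), and
#'   `crfs` (named list containing the all-cause log-linear CRF).
#' @export
fixture_endpoints <- function() {
  endpoints <- utils::read.csv(.extdata("baseline_incidence.csv"))
  populations <- utils::read.csv(.extdata("synthetic_populations.csv"))
  list(
    endpoints = endpoints,
    populations = populations,
    crfs = list(allcause_loglin = crf_log_linear(
      rr = 1.062, rr_low = 1.04, rr_high = 1.083,
      increment = 10, cutoff = 10
    ))
  )
}

#' Bundled reference impact summary
#'
#' Attributable proportion (percent), excess cases and attributable cases
#' per 100,000 for each city and endpoint, as reported in the seven-city
#' 2019-2020 assessment these fixtures accompany. Used as a consistency
#' surface for the attributable-rate and excess-case arithmetic.
#'
#' @return Data frame `city, endpoint, ap_percent, excess_cases, per_100k`.
#' @export
reference_impacts <- function() {
  utils::read.csv(.extdata("impact_summary.csv"))
}

#' Bundled reference exposure summary
#'
#' Annual max/min/mean/SD of daily PM2.5 and of five meteorological
#' variables for the seven cities, in the layout produced by
#' [exposure_summary_table].
#'
#' @return Data frame `city, variable, max, min, mean, sd`.
#' @export
reference_exposure_summary <- function() {
  utils::read.csv(.extdata("exposure_summary.csv"))
}
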