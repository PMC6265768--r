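#' Configuration for the synthetic cold-mortality study generator
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults describe an England-like study: 44 areas observed over the nine
#' calendar years 2007--2015, around 20 weather stations per area with 10%
#' of days missing at random, a seasonal mean temperature cycle with AR(1)
#' day-to-day persistence, and winter death counts with seasonal
#' confounding, day-of-week structure, overdispersion, and a cold effect
#' that is linear below a threshold and distributed over lags 0--28.
#'
#' @param n_areas number of areas to simulate.
#' @param years number of full calendar years, starting at `start_year`.
#' @param start_year first calendar year of the study.
#' @param stations_per_area weather stations observing each area.
#' @param missing_rate probability that a station-day is missing, in `[0, 1)`.
#' @param temp_mean_annual annual mean temperature, degrees C.
#' @param temp_seasonal_amplitude seasonal half-range, degrees C; the mean
#'   cycle peaks in mid-July and troughs in mid-January.
#' @param temp_ar1_coef AR(1) coefficient of daily temperature anomalies,
#'   strictly inside `(-1, 1)`.
#' @param temp_noise_sd innovation standard deviation of the anomaly process.
#' @param station_offset_sd between-station systematic offset SD, degrees C.
#' @param station_noise_sd day-level station measurement noise SD, degrees C.
#' @param baseline_daily_deaths expected deaths per day with all effects off.
#' @param seasonal_mortality_amplitude log-scale amplitude of the winter
#'   mortality peak (mid-January maximum).
#' @param dow_effects seven log-scale day-of-week offsets (Sunday first),
#'   summing to zero.
#' @param cold_threshold temperature below which cold increases mortality.
#' @param cumulative_log_rr_per_degC log relative risk per degree of cold
#'   excess, summed over lags 0--28.
#' @param lag_weight_shape how the cumulative cold effect is spread over
#'   lags: `"constant"`, `"linear-decay"`, or `"spline-bump"`.
#' @param max_lag largest lag (days) carrying cold effect.
#' @param overdispersion variance inflation factor `>= 1`; counts are drawn
#'   negative binomial with variance `overdispersion * mean` (Poisson at 1).
#' @param fuel_poverty_range range (%) from which area fuel-poverty values
#'   are drawn uniformly.
#' @param seed integer seed; all generator functions derive their random
#'   streams from it, so a config fully determines the simulated study.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_areas = 44L,
                       years = 9L,
                       start_year = 2007L,
                       stations_per_area = 20L,
                       missing_rate = 0.1,
                       temp_mean_annual = 9.5,
                       temp_seasonal_amplitude = 6.5,
                       temp_ar1_coef = 0.7,
                       temp_noise_sd = 1.8,
                       station_offset_sd = 0.8,
                       station_noise_sd = 0.6,
                       baseline_daily_deaths = 30,
                       seasonal_mortality_amplitude = 0.15,
                       dow_effects = c(0.02, -0.01, -0.01, -0.01, -0.01, 0.0, 0.02),
                       cold_threshold = 13,
                       cumulative_log_rr_per_degC = log(1.35) / 17.27,
                       lag_weight_shape = c("spline-bump", "constant", "linear-decay"),
                       max_lag = 28L,
                       overdispersion = 1.5,
                       fuel_poverty_range = c(7, 15),
                       seed = 1L) {
  lag_weight_shape <- match.arg(lag_weight_shape)
  cfg <- list(
    n_areas = as.integer(n_areas), years = as.integer(years),
    start_year = as.integer(start_year),
    stations_per_area = as.integer(stations_per_area),
    missing_rate = missing_rate,
    temp_mean_annual = temp_mean_annual,
    temp_seasonal_amplitude = temp_seasonal_amplitude,
    temp_ar1_coef = temp_ar1_coef, temp_noise_sd = temp_noise_sd,
    station_offset_sd = station_offset_sd,
    station_noise_sd = station_noise_sd,
    baseline_daily_deaths = baseline_daily_deaths,
    seasonal_mortality_amplitude = seasonal_mortality_amplitude,
    dow_effects = dow_effects,
    cold_threshold = cold_threshold,
    cumulative_log_rr_per_degC = cumulative_log_rr_per_degC,
    lag_weight_shape = lag_weight_shape, max_lag = as.integer(max_lag),
    overdispersion = overdispersion,
    fuel_poverty_range = fuel_poverty_range,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot_msg <- function(ok, msg) if (!ok) abort(msg)
  stopifnot_msg(cfg$n_areas >= 1 && cfg$years >= 1 && cfg$stations_per_area >= 1,
                "n_areas, years and stations_per_area must all be >= 1")
  stopifnot_msg(cfg$missing_rate >= 0 && cfg$missing_rate < 1,
                "missing_rate must lie in [0, 1)")
  stopifnot_msg(abs(cfg$temp_ar1_coef) < 1,
                "temp_ar1_coef must lie strictly inside (-1, 1)")
  stopifnot_msg(cfg$overdispersion >= 1,
                "overdispersion must be >= 1 (1 = Poisson)")
  stopifnot_msg(length(cfg$dow_effects) == 7L,
                "dow_effects must have length 7")
  stopifnot_msg(abs(sum(cfg$dow_effects)) < 1e-8,
                "dow_effects must sum to zero (identifiability convention)")
  stopifnot_msg(cfg$max_lag >= 0L, "max_lag must be >= 0")
  invisible(cfg)
}

#' Lag-weight profiles for the generated cold effect
#'
#' Returns nonnegative weights over lags `0:max_lag` summing to one; the
#' generator multiplies them by the cumulative per-degree log relative risk
#' to spread the cold effect over the lag window. Three shapes are offered
#' because the true lag profile of cold-related mortality is not identified
#' by the fitted cumulative risk, and recovery should hold under several.
#'
#' @param shape `"constant"` (flat), `"linear-decay"` (weight declining
#'   linearly to the last lag), or `"spline-bump"` (smooth bump peaking
#'   around lag 6, the classic delayed cold-mortality profile).
#' @param max_lag largest lag, default 28.
#' @return numeric vector of length `max_lag + 1` summing to 1.
#' @examples
#' sum(lag_weights("spline-bump"))  # 1
#' @export
lag_weights <- function(shape = c("spline-bump", "constant", "linear-decay"),
                        max_lag = 28L) {
  shape <- match.arg(shape)
  l <- 0:max_lag
  w <- switch(shape,
    "constant"     = rep(1, length(l)),
    "linear-decay" = (max_lag + 1 - l),
    "spline-bump"  = exp(-((l - 6) / 5)^2)
  )
  w / sum(w)
}

study_dates <- function(config, pre_period = FALSE) {
  start <- as.Date(sprintf("%d-01-01", config$start_year))
  end <- as.Date(sprintf("%d-12-31", config$start_year + config$years - 1L))
  if (pre_period) start <- start - config$max_lag
  seq(start, end, by = "day")
}

seasonal_temp <- function(date, config) {
  doy <- day_of_year(date)
  # trough in mid-January (day 15), peak half a year later
  config$temp_mean_annual -
    config$temp_seasonal_amplitude * cos(2 * pi * (doy - 15) / 365.25)
}

#' Simulate the latent daily mean temperature of one area
#'
#' Daily mean temperature is a seasonal cycle (coldest mid-January) plus a
#' stationary AR(1) anomaly. The series starts `max_lag` days before
#' 1 January of `start_year` so that every study day, including the first,
#' has a complete lagged exposure history; pre-period days are flagged.
#'
#' @param config a [sim_config()].
#' @param area_index which area (changes the random stream, not the
#'   marginal distribution).
#' @return tibble with columns `date`, `temp`, `pre_period`.
#' @export
sim_temperature <- function(config, area_index = 1L) {
  validate_sim_config(config)
  dates <- study_dates(config, pre_period = TRUE)
  n <- length(dates)
  e <- with_seed(config$seed + 7919L * area_index, {
    innov <- rnorm(n, 0, config$temp_noise_sd)
    e <- numeric(n)
    # start the anomaly at its stationary distribution
    e[1] <- if (config$temp_noise_sd > 0) {
      rnorm(1, 0, config$temp_noise_sd / sqrt(1 - config$temp_ar1_coef^2))
    } else 0
    for (t in seq_len(n)[-1]) e[t] <- config$temp_ar1_coef * e[t - 1] + innov[t]
    e
  })
  tibble::tibble(
    date = dates,
    temp = seasonal_temp(dates, config) + e,
    pre_period = dates < as.Date(sprintf("%d-01-01", config$start_year))
  )
}

#' Simulate multi-station observations of an area temperature series
#'
#' Each station reports the latent area series plus a fixed systematic
#' offset and day-level measurement noise, with days deleted independently
#' at `missing_rate`. At least one station is guaranteed to retain at least
#' 75% coverage so the area always survives the composite coverage filter.
#'
#' @param true_series tibble from [sim_temperature()] (pre-period rows are
#'   dropped; stations observe study days only).
#' @param config a [sim_config()].
#' @param area_index area whose stations are drawn (sets the stream).
#' @return tibble with columns `station_id`, `date`, `temp`; missing
#'   station-days are absent rows.
#' @export
sim_stations <- function(true_series, config, area_index = 1L) {
  validate_sim_config(config)
  obs <- true_series[!true_series$pre_period, c("date", "temp")]
  n <- nrow(obs)
  with_seed(config$seed + 7919L * area_index + 1L, {
    stations <- purrr::map(seq_len(config$stations_per_area), function(s) {
      offset <- rnorm(1, 0, config$station_offset_sd)
      keep <- runif(n) >= config$missing_rate
      tibble::tibble(
        station_id = sprintf("st%02d", s),
        date = obs$date[keep],
        temp = obs$temp[keep] + offset + rnorm(sum(keep), 0, config$station_noise_sd)
      )
    })
    coverages <- purrr::map_dbl(stations, ~ nrow(.x) / n)
    if (max(coverages) < 0.75) {
      # rare under extreme missing_rate: thin station 1's deletions to 75%
      s1 <- which.max(coverages)
      missing_dates <- obs$date[!obs$date %in% stations[[s1]]$date]
      n_restore <- ceiling(0.75 * n) - nrow(stations[[s1]])
      restore <- sort(sample(missing_dates, n_restore))
      extra <- tibble::tibble(
        station_id = stations[[s1]]$station_id[1],
        date = restore,
        temp = obs$temp[match(restore, obs$date)] +
          rnorm(length(restore), 0, config$station_noise_sd)
      )
      stations[[s1]] <- dplyr::arrange(dplyr::bind_rows(stations[[s1]], extra), date)
    }
    dplyr::bind_rows(stations)
  })
}

#' Simulate daily death counts with a distributed-lag cold effect
#'
#' The log mean is `log(baseline) + seasonal + day-of-week +
#' beta * sum_l w_l * max(0, h - T_{t-l})`, with `beta` the cumulative log
#' relative risk per degree of cold excess, `w` the lag weights, and `h` the
#' cold threshold. Counts are negative binomial with variance
#' `overdispersion * mean`, reducing to Poisson when `overdispersion = 1`.
#' The pre-period rows of `true_series` supply lagged exposure for the first
#' `max_lag` study days; deaths are returned for study days only.
#'
#' This mean structure is exactly representable by the threshold
#' distributed-lag design when the same threshold and lag weights are
#' supplied, which is what makes noise-free recovery checks possible.
#'
#' @param true_series tibble from [sim_temperature()], including pre-period.
#' @param config a [sim_config()].
#' @param weights lag weights over `0:max_lag`; defaults to
#'   `lag_weights(config$lag_weight_shape)`.
#' @param beta cumulative log RR per degree; defaults to
#'   `config$cumulative_log_rr_per_degC`.
#' @param area_index area (sets the stream).
#' @return tibble with columns `date`, `deaths`, `mu` (the true mean).
#' @export
sim_deaths <- function(true_series, config, weights = NULL, beta = NULL,
                       area_index = 1L) {
  validate_sim_config(config)
  weights <- weights %||% lag_weights(config$lag_weight_shape, config$max_lag)
  beta <- beta %||% config$cumulative_log_rr_per_degC
  L <- config$max_lag
  if (length(weights) != L + 1L) {
    abort(sprintf("weights must cover lags 0..%d (length %d)", L, L + 1L))
  }
  stopifnot(nrow(true_series) > L)
  z <- cold_excess(true_series$temp, config$cold_threshold)
  # lagged exposure term: rows t = L+1 .. n of the full series are study days
  Zl <- stats::embed(z, L + 1L)         # columns are lag 0, 1, ..., L
  lag_term <- drop(Zl %*% (beta * weights))
  keep <- !true_series$pre_period
  if (sum(keep) != nrow(Zl)) {
    abort("true_series must carry exactly max_lag pre-period days")
  }
  dates <- true_series$date[keep]
  doy <- day_of_year(dates)
  wd <- as.POSIXlt(dates)$wday + 1L     # 1 = Sunday
  log_mu <- log(config$baseline_daily_deaths) +
    config$seasonal_mortality_amplitude * cos(2 * pi * (doy - 15) / 365.25) +
    config$dow_effects[wd] +
    lag_term
  mu <- exp(log_mu)
  deaths <- with_seed(config$seed + 7919L * area_index + 2L, {
    if (config$overdispersion == 1) {
      rpois(length(mu), mu)
    } else {
      rnbinom(length(mu), mu = mu, size = mu / (config$overdispersion - 1))
    }
  })
  tibble::tibble(date = dates, deaths = as.integer(deaths), mu = mu)
}

#' Simulate a complete multi-area study with known ground truth
#'
#' Runs the temperature, station and mortality generators for every area and
#' collects the ground truth needed to validate downstream estimates: the
#' true cumulative log RR per degree, the lag-weight profile, the realised
#' winter first-percentile and maximum temperatures with the implied true RR
#' between them, and an area fuel-poverty percentage drawn uniformly from
#' `config$fuel_poverty_range`.
#'
#' @param config a [sim_config()].
#' @param beta_by_area optional vector (length `n_areas`) of area-specific
#'   cumulative log RRs per degree, overriding the common config value;
#'   used to plant between-area heterogeneity.
#' @return list with tibbles `stations` (`area_id, station_id, date, temp`),
#'   `deaths` (`area_id, date, deaths`), `latent` (`area_id, date, temp,
#'   pre_period`), `truth` (one row per area), and the `config`.
#' @export
simulate_study <- function(config = sim_config(), beta_by_area = NULL) {
  validate_sim_config(config)
  beta_by_area <- beta_by_area %||%
    rep(config$cumulative_log_rr_per_degC, config$n_areas)
  stopifnot(length(beta_by_area) == config$n_areas)
  w <- lag_weights(config$lag_weight_shape, config$max_lag)
  fp <- with_seed(config$seed + 13L, {
    runif(config$n_areas, config$fuel_poverty_range[1], config$fuel_poverty_range[2])
  })
  areas <- purrr::map(seq_len(config$n_areas), function(a) {
    area_id <- sprintf("area%02d", a)
    latent <- sim_temperature(config, a)
    stations <- sim_stations(latent, config, a)
    deaths <- sim_deaths(latent, config, weights = w,
                         beta = beta_by_area[a], area_index = a)
    winter_temp <- latent$temp[!latent$pre_period & is_winter(latent$date)]
    p1 <- unname(quantile(winter_temp, 0.01, type = 7))
    tmax <- max(winter_temp)
    span <- cold_excess(p1, config$cold_threshold) -
      cold_excess(tmax, config$cold_threshold)
    list(
      stations = dplyr::mutate(stations, area_id = area_id, .before = 1),
      deaths = tibble::tibble(area_id = area_id, date = deaths$date,
                              deaths = deaths$deaths),
      latent = dplyr::mutate(latent, area_id = area_id, .before = 1),
      truth = tibble::tibble(
        area_id = area_id,
        beta_per_degC = beta_by_area[a],
        winter_p1 = p1, winter_max = tmax,
        true_rr_p1_max = exp(beta_by_area[a] * span),
        fuel_poverty = fp[a]
      )
    )
  })
  list(
    stations = dplyr::bind_rows(purrr::map(areas, "stations")),
    deaths = dplyr::bind_rows(purrr::map(areas, "deaths")),
    latent = dplyr::bind_rows(purrr::map(areas, "latent")),
    truth = dplyr::bind_rows(purrr::map(areas, "truth")),
    lag_weights = w,
    config = config
  )
}

#' Write a simulated study to delimited files
#'
#' Station series and death counts go to CSV (ISO-8601 dates), the ground
#' truth and configuration to a YAML file, all under `dir`.
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- c(sprintf("seed: %d", sim$config$seed),
            sprintf("n_areas: %d", sim$config$n_areas))
  write_output_table(sim$stations, file.path(dir, "stations.csv"), meta)
  write_output_table(sim$deaths, file.path(dir, "deaths.csv"), meta)
  write_output_table(sim$truth, file.path(dir, "ground_truth.csv"), meta)
  if (requireNamespace("yaml", quietly = TRUE)) {
    cfg <- unclass(sim$config)
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  }
  invisible(dir)
}
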