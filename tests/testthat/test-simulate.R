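test_that("config validation rejects impossible settings", {
  expect_error(sim_config(temp_ar1_coef = 1), "strictly inside")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(overdispersion = 0.5), "overdispersion")
  expect_error(sim_config(dow_effects = rep(0.1, 7)), "sum to zero")
})

test_that("lag weights are nonnegative and sum to one for every shape", {
  for (shape in c("constant", "linear-decay", "spline-bump")) {
    w <- lag_weights(shape)
    expect_length(w, 29L)
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
})

test_that("noise-free temperature degenerates to its deterministic parts", {
  cfg <- tiny_config(temp_seasonal_amplitude = 0, temp_noise_sd = 0)
  tt <- sim_temperature(cfg)
  expect_true(all(tt$temp == cfg$temp_mean_annual))

  cfg2 <- tiny_config(temp_seasonal_amplitude = 7, temp_noise_sd = 0,
                      temp_ar1_coef = 0)
  tt2 <- sim_temperature(cfg2)
  one_year <- tt2[format(tt2$date, "%Y") == "2007", ]
  # seasonal half-range 7 gives a 14 degree winter-to-summer swing,
  # coldest in mid-January
  expect_equal(max(one_year$temp) - min(one_year$temp), 14, tolerance = 1e-3)
  expect_equal(format(one_year$date[which.min(one_year$temp)], "%m"), "01")
})

test_that("deseasonalised series has the configured lag-1 autocorrelation", {
  cfg <- sim_config(n_areas = 1L, years = 9L, seed = 1L)
  tt <- sim_temperature(cfg)
  resid <- tt$temp - (cfg$temp_mean_annual -
    cfg$temp_seasonal_amplitude *
      cos(2 * pi * (as.integer(format(tt$date, "%j")) - 15) / 365.25))
  acf1 <- cor(resid[-1], resid[-length(resid)])
  expect_lt(abs(acf1 - cfg$temp_ar1_coef), 0.05)
})

test_that("stations reproduce the latent series when noise and missingness are off", {
  cfg <- tiny_config(missing_rate = 0, station_offset_sd = 0,
                     station_noise_sd = 0)
  tt <- sim_temperature(cfg)
  st <- sim_stations(tt, cfg)
  study <- tt[!tt$pre_period, ]
  for (s in unique(st$station_id)) {
    sub <- st[st$station_id == s, ]
    expect_equal(sub$date, study$date)
    expect_equal(sub$temp, study$temp)
  }
})

test_that("station retention matches the binomial deletion rate", {
  cfg <- sim_config(n_areas = 1L, years = 3L, stations_per_area = 8L,
                    missing_rate = 0.3, seed = 7L)
  tt <- sim_temperature(cfg)
  st <- sim_stations(tt, cfg)
  n_days <- sum(!tt$pre_period)
  frac <- tapply(st$date, st$station_id, length) / n_days
  # binomial band around 0.7, widened to the station guaranteed >= 75%
  expect_true(all(frac >= 0.7 - 3 * sqrt(0.3 * 0.7 / n_days)))
  expect_true(all(frac <= 0.75 + 1e-9))
  # contract: at least one station passes the 75% coverage filter
  cfg2 <- sim_config(n_areas = 1L, years = 2L, stations_per_area = 3L,
                     missing_rate = 0.6, seed = 7L)
  st2 <- sim_stations(sim_temperature(cfg2), cfg2)
  n2 <- sum(!sim_temperature(cfg2)$pre_period)
  expect_gte(max(tapply(st2$date, st2$station_id, length)) / n2, 0.75)
})

test_that("identical config and seed give bit-identical output", {
  cfg <- tiny_config(missing_rate = 0.2)
  expect_identical(sim_temperature(cfg), sim_temperature(cfg))
  tt <- sim_temperature(cfg)
  expect_identical(sim_stations(tt, cfg), sim_stations(tt, cfg))
  expect_identical(sim_deaths(tt, cfg), sim_deaths(tt, cfg))
  expect_identical(simulate_study(tiny_config()), simulate_study(tiny_config()))
})

test_that("null-effect mortality has the configured baseline mean", {
  cfg <- sim_config(n_areas = 1L, years = 9L, baseline_daily_deaths = 25,
                    seasonal_mortality_amplitude = 0,
                    dow_effects = rep(0, 7), seed = 3L)
  dd <- sim_deaths(sim_temperature(cfg), cfg, beta = 0)
  se <- sd(dd$deaths) / sqrt(nrow(dd))
  expect_lt(abs(mean(dd$deaths) - 25), 3 * se)
})

test_that("overdispersion controls the variance-to-mean ratio", {
  base <- list(n_areas = 1L, years = 9L, baseline_daily_deaths = 25,
               seasonal_mortality_amplitude = 0, dow_effects = rep(0, 7),
               seed = 4L)
  cfg1 <- do.call(sim_config, c(base, overdispersion = 1))
  dd1 <- sim_deaths(sim_temperature(cfg1), cfg1, beta = 0)
  ratio1 <- var(dd1$deaths) / mean(dd1$deaths)
  expect_lt(abs(ratio1 - 1), 0.1)  # ~3300 days; MC sd of the ratio ~ 0.025

  cfg2 <- do.call(sim_config, c(base, overdispersion = 2))
  dd2 <- sim_deaths(sim_temperature(cfg2), cfg2, beta = 0)
  ratio2 <- var(dd2$deaths) / mean(dd2$deaths)
  expect_lt(abs(ratio2 - 2), 0.3)
})

test_that("generated mean equals the closed-form mean on the design", {
  # beta chosen so a 10 degree cold excess carries cumulative RR 1.5
  cfg <- sim_config(n_areas = 1L, years = 3L, seed = 5L,
                    cumulative_log_rr_per_degC = log(1.5) / 10)
  tt <- sim_temperature(cfg)
  dd <- sim_deaths(tt, cfg)
  w <- lag_weights(cfg$lag_weight_shape)
  z <- cold_excess(tt$temp, cfg$cold_threshold)
  # independent recomputation of the lagged mean, day by day
  study_idx <- which(!tt$pre_period)
  mu_check <- sapply(study_idx, function(t) {
    lagsum <- sum(cfg$cumulative_log_rr_per_degC * w * z[t - (0:28)])
    doy <- as.integer(format(tt$date[t], "%j"))
    wd <- as.POSIXlt(tt$date[t])$wday + 1L
    exp(log(cfg$baseline_daily_deaths) +
          cfg$seasonal_mortality_amplitude * cos(2 * pi * (doy - 15) / 365.25) +
          cfg$dow_effects[wd] + lagsum)
  })
  expect_equal(dd$mu, mu_check, tolerance = 1e-12)
  # and the planted contrast is recovered from the true means: days with a
  # 10-degree mean lagged excess carry 1.5 times the baseline-seasonal mean
  excess10 <- exp(sum(cfg$cumulative_log_rr_per_degC * w * 10))
  expect_equal(excess10, 1.5, tolerance = 1e-12)
})

test_that("ground truth in simulate_study matches its own definition", {
  sim <- simulate_study(tiny_config(n_areas = 2L))
  expect_equal(nrow(sim$truth), 2L)
  for (i in 1:2) {
    lat <- sim$latent[sim$latent$area_id == sim$truth$area_id[i], ]
    wt <- lat$temp[!lat$pre_period & is_winter(lat$date)]
    expect_equal(sim$truth$winter_p1[i],
                 unname(quantile(wt, 0.01, type = 7)))
    expect_equal(sim$truth$winter_max[i], max(wt))
  }
  expect_true(all(sim$truth$fuel_poverty >= 7 & sim$truth$fuel_poverty <= 15))
})
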