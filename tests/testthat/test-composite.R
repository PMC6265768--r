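make_station <- function(id, dates, temp) {
  tibble::tibble(station_id = id, date = dates, temp = temp)
}

test_that("coverage filter keeps and drops stations around the threshold", {
  days <- seq(as.Date("2010-01-01"), by = "day", length.out = 100)
  st <- dplyr::bind_rows(
    make_station("a", days[1:80], rep(5, 80)),    # 80% coverage
    make_station("b", days[1:70], rep(5, 70))     # 70% coverage
  )
  kept <- coverage_filter(st, 0.75, study_days = days)
  expect_setequal(unique(kept$station_id), "a")
  expect_error(coverage_filter(st, 0.85, study_days = days, area_id = "X"),
               "no station in X")
})

test_that("retained set equals a brute-force recount of non-missing days", {
  days <- seq(as.Date("2010-01-01"), by = "day", length.out = 200)
  set.seed(11)
  st <- dplyr::bind_rows(lapply(1:10, function(i) {
    keep <- sample(200, sample(120:200, 1))
    make_station(sprintf("s%02d", i), days[keep], rnorm(length(keep), 5))
  }))
  kept <- coverage_filter(st, 0.75, study_days = days)
  manual <- vapply(split(st, st$station_id),
                   function(d) sum(!is.na(d$temp)) / 200, numeric(1))
  expect_setequal(unique(kept$station_id), names(manual)[manual >= 0.75])
})

test_that("composite of offset stations removes the offset symmetrically", {
  days <- seq(as.Date("2010-01-01"), by = "day", length.out = 60)
  v <- 5 + 3 * sin(1:60 / 5)
  st <- dplyr::bind_rows(make_station("a", days, v),
                         make_station("b", days, v + 2))
  comp <- composite_mean(st, study_days = days)
  expect_equal(comp$temp, v + 1, tolerance = 1e-12)
  expect_true(all(comp$n_stations == 2L))
})

test_that("a lone station passes through unchanged on its reporting days", {
  days <- seq(as.Date("2010-01-01"), by = "day", length.out = 50)
  v <- rnorm(50, 4)
  comp <- composite_mean(make_station("a", days[-10], v[-10]),
                         study_days = days)
  expect_equal(comp$temp[-10], v[-10], tolerance = 1e-12)
  expect_true(is.na(comp$temp[10]))
})

test_that("composite equals an independently coded anomaly average", {
  cfg <- tiny_config(missing_rate = 0.2, seed = 9L)
  tt <- sim_temperature(cfg)
  st <- sim_stations(tt, cfg)
  days <- tt$date[!tt$pre_period]
  comp <- composite_mean(st, study_days = days)

  # brute force: per-day count, shared days, station means, anomaly average
  ids <- unique(st$station_id)
  counts <- table(st$date)
  shared <- as.Date(names(counts)[counts >= 2])
  st_mean <- sapply(ids, function(s) {
    d <- st[st$station_id == s, ]
    onshared <- d$date %in% shared
    if (any(onshared)) mean(d$temp[onshared]) else mean(d$temp)
  })
  pooled <- mean(st$temp)
  manual <- sapply(days, function(day) {
    d <- st[st$date == day, ]
    if (nrow(d) == 0) return(NA_real_)
    mean(d$temp - st_mean[d$station_id]) + pooled
  })
  expect_equal(comp$temp, unname(manual), tolerance = 1e-10)
})

test_that("imputation is the identity on complete series and fills midpoints", {
  days <- seq(as.Date("2010-01-01"), by = "day", length.out = 101)
  comp <- tibble::tibble(area_id = "a", date = days, temp = rep(5, 101),
                         n_stations = 1L)
  out <- impute_missing(comp)
  expect_equal(out$temp, comp$temp)
  expect_false(any(out$imputed))

  comp$temp[50] <- 4; comp$temp[52] <- 6; comp$temp[51] <- NA
  out2 <- impute_missing(comp)
  expect_equal(out2$temp[51], 5, tolerance = 0.01)
  expect_equal(out2$temp[-51], comp$temp[-51])  # observed days untouched
})

test_that("imputation guards fire on sparse series and long gaps", {
  days <- seq(as.Date("2010-01-01"), by = "day", length.out = 100)
  comp <- tibble::tibble(date = days, temp = rnorm(100, 5))
  sparse <- comp; sparse$temp[1:20] <- NA
  expect_error(impute_missing(sparse), "need >= 90%")
  gappy <- comp; gappy$temp[30:38] <- NA
  expect_error(impute_missing(gappy, max_gap = 5), "exceeding max_gap")
})

test_that("hold-out imputation error stays below the residual spread", {
  cfg <- sim_config(n_areas = 1L, years = 3L, seed = 21L)
  tt <- sim_temperature(cfg)
  study <- tt[!tt$pre_period, ]
  comp <- tibble::tibble(date = study$date, temp = study$temp)
  set.seed(22)
  holes <- sample(nrow(comp), round(0.05 * nrow(comp)))
  withheld <- comp$temp[holes]
  comp$temp[holes] <- NA
  out <- impute_missing(comp)
  mae <- mean(abs(out$temp[holes] - withheld))
  resid_sd <- sd(study$temp - (cfg$temp_mean_annual -
    cfg$temp_seasonal_amplitude *
      cos(2 * pi * (as.integer(format(study$date, "%j")) - 15) / 365.25)))
  expect_lt(mae, resid_sd)
})

test_that("temperature summaries follow type-7 order statistics", {
  days <- seq(as.Date("2010-11-01"), by = "day", length.out = 101)
  const <- tibble::tibble(date = days, temp = rep(3.2, 101))
  s <- summarize_temperature(const)
  expect_equal(unlist(s), c(lowest = 3.2, p1 = 3.2, median = 3.2,
                            highest = 3.2))

  ramp <- tibble::tibble(date = days, temp = 0:100)
  s2 <- summarize_temperature(ramp, winter_only = FALSE)
  expect_equal(s2$p1, 1)        # 0.01 * (101 - 1) lands on the 2nd value
  expect_equal(s2$median, 50)
  expect_equal(s2$lowest, 0)
  expect_equal(s2$highest, 100)

  summer <- tibble::tibble(date = as.Date("2010-07-01") + 0:10, temp = 1:11)
  expect_error(summarize_temperature(summer), "no winter days")
})

test_that("summaries are invariant to station order and idempotent on complete data", {
  cfg <- tiny_config(missing_rate = 0.1, seed = 30L)
  tt <- sim_temperature(cfg)
  st <- sim_stations(tt, cfg)
  days <- tt$date[!tt$pre_period]
  a <- build_composite(st, study_days = days)
  b <- build_composite(st[sample(nrow(st)), ], study_days = days)
  expect_equal(summarize_temperature(a), summarize_temperature(b))
  # a second pass over the already-complete composite changes nothing
  again <- impute_missing(a[c("area_id", "date", "temp", "n_stations")])
  expect_equal(again$temp, a$temp)
})
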