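# One moderate fitted model reused across blocks.
fit_example <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      cfg <- sim_config(n_areas = 1L, years = 5L, seed = 77L)
      panel <- sim_winter_panel(cfg)
      dsn <- assemble_design(panel, threshold = cfg$cold_threshold)
      memo <<- fit_quasipoisson(dsn)
    }
    memo
  }
})

test_that("null cold coefficients give a relative risk of exactly 1", {
  fit <- fit_example()
  fit$beta[fit$design$blocks$cold] <- 0
  est <- rr_between(fit, -3, 10)
  expect_equal(est$rr, 1)
  expect_lte(est$lo, 1)
  expect_gte(est$hi, 1)
  sens <- rr_sensitivity_fixed(fit)
  expect_equal(sens$rr, 1)
})

test_that("identity lag basis recovers the closed-form risk", {
  panel <- toy_panel(151, temp = rnorm(151, 4, 3))
  dsn <- assemble_design(panel, threshold = 20, lag_type = "identity")
  fit <- fit_quasipoisson(dsn)
  # plant coefficients summing to b = ln(1.35)/17.27 per degree
  b <- log(1.35) / 17.27
  fit$beta[dsn$blocks$cold] <- b * lag_weights("spline-bump")
  est <- rr_between(fit, -2.97, 14.30)   # both below the threshold of 20
  expect_equal(est$rr, 1.35, tolerance = 1e-12)
})

test_that("risks compose multiplicatively below the threshold", {
  fit <- fit_example()
  h <- fit$design$h
  r1 <- rr_between(fit, -5, 2)
  r2 <- rr_between(fit, 2, 8)
  r3 <- rr_between(fit, -5, 8)
  expect_equal(r1$rr * r2$rr, r3$rr, tolerance = 1e-10)
  # monotone in the contrast span for a positive cumulative effect
  if (r3$log_rr > 0) {
    expect_gt(r3$rr, r1$rr)
    expect_gt(r3$rr, r2$rr)
  }
  expect_error(rr_between(fit, 5, 5), "colder")
})

test_that("the fixed 0 vs 13 sensitivity contrast is pure delegation", {
  fit <- fit_example()
  expect_equal(rr_sensitivity_fixed(fit), rr_between(fit, 0, 13))
})

test_that("confidence intervals are symmetric on the log scale", {
  fit <- fit_example()
  est <- rr_between(fit, -4, 9)
  expect_equal(log(est$rr) - log(est$lo), log(est$hi) - log(est$rr),
               tolerance = 1e-9)
  expect_true(est$lo <= est$rr && est$rr <= est$hi)
})

test_that("attribution closed forms hold on a hand-built single day", {
  # a single usable day with 10 deaths and a known lagged excess history
  set.seed(55)
  z_hist <- runif(29, 0.5, 2)                 # lag 0 .. 28 cold excess
  dsn <- structure(list(
    B = lag_basis_matrix(28, "identity"),
    lagged = matrix(z_hist, nrow = 1),
    blocks = list(cold = 2:30),
    y = 10L, h = 5, max_lag = 28L
  ), class = "threshold_dlm_design")
  beta <- setNames(numeric(30), c("(Intercept)", paste0("cold", 1:29)))
  beta[2:30] <- log(2) / sum(z_hist)          # makes a_t = ln 2
  fit <- structure(list(beta = beta, vcov = diag(30), design = dsn,
                        converged = TRUE), class = "qp_fit")
  burden <- attributable_burden(fit)
  expect_equal(burden$attributable_number, 5, tolerance = 1e-12)
  expect_equal(burden$attributable_fraction, 50, tolerance = 1e-12)
  expect_equal(burden$total_deaths, 10L)
  # eta = 0 gives exactly zero burden
  fit$beta[2:30] <- 0
  zero <- attributable_burden(fit)
  expect_identical(zero$attributable_number, 0)
  expect_identical(zero$attributable_fraction, 0)
})

test_that("attributable number equals an independent per-day recomputation", {
  fit <- fit_example()
  dsn <- fit$design
  burden <- attributable_burden(fit)
  eta <- drop(dsn$B %*% fit$beta[dsn$blocks$cold])
  z <- cold_excess(dsn$panel$temp, dsn$h)
  an <- 0
  total <- 0
  for (k in seq_along(dsn$usable)) {
    t <- dsn$usable[k]
    a_t <- sum(eta * z[t - (0:dsn$max_lag)])
    y_t <- dsn$panel$deaths[t]
    an <- an + (1 - exp(-a_t)) * y_t
    total <- total + y_t
  }
  expect_equal(burden$attributable_number, an, tolerance = 1e-10)
  expect_equal(burden$attributable_fraction, 100 * an / total,
               tolerance = 1e-10)
})

test_that("attributable fraction is invariant to integer rescaling of deaths", {
  fit <- fit_example()
  dsn3 <- fit$design
  dsn3$y <- dsn3$y * 3L
  dsn3$panel$deaths <- dsn3$panel$deaths * 3L
  fit3 <- fit
  fit3$design <- dsn3
  b1 <- attributable_burden(fit)
  b3 <- attributable_burden(fit3)
  expect_equal(b3$attributable_number, 3 * b1$attributable_number)
  expect_equal(b3$attributable_fraction, b1$attributable_fraction)
})

test_that("period splitting assigns winters whole and drops the transition", {
  dates <- seq(as.Date("2006-11-01"), as.Date("2016-03-31"), by = "day")
  dates <- dates[is_winter(dates)]
  panel <- tibble::tibble(date = dates, temp = 5, deaths = 1L)
  sp <- split_periods(panel)
  expect_true(as.Date("2009-01-15") %in% sp$pre$date)
  expect_true(as.Date("2014-01-15") %in% sp$post$date)
  expect_false(as.Date("2011-12-15") %in% sp$pre$date)
  expect_false(as.Date("2011-12-15") %in% sp$post$date)
  expect_false(as.Date("2011-01-15") %in% c(sp$pre$date, sp$post$date))
  expect_length(intersect(sp$pre$date, sp$post$date), 0L)
  # every retained winter is entirely in one period
  expect_setequal(unique(winter_label(sp$pre$date)), 2007:2010)
  expect_setequal(unique(winter_label(sp$post$date)), 2013:2015)
  expect_error(split_periods(panel, pre_january = 2013, post_january = 2013),
               "overlap")
  expect_error(split_periods(panel[winter_label(panel$date) < 2012, ]),
               "post period is empty")
})

test_that("comparison of two risk estimates follows the z formula", {
  same <- tibble::tibble(rr = 1.3, lo = 1.2, hi = 1.41)
  cmp0 <- compare_rr(same, same)
  expect_equal(cmp0$z, 0)
  expect_equal(cmp0$p_value, 1)
  expect_false(cmp0$significant)

  # national pre/post contrast for the youngest age band: a clear decline
  pre <- tibble::tibble(rr = 1.34, lo = 1.23, hi = 1.45)
  post <- tibble::tibble(rr = 1.09, lo = 1.00, hi = 1.19)
  cmp <- compare_rr(pre, post)
  expect_gt(abs(cmp$z), 1.96)
  expect_true(cmp$significant)
  manual_z <- (log(1.34) - log(1.09)) /
    sqrt(se_from_ci(1.23, 1.45)^2 + se_from_ci(1.00, 1.19)^2)
  expect_equal(cmp$z, manual_z)
  expect_error(compare_rr(pre, tibble::tibble(rr = 1, lo = 1, hi = 1)),
               "degenerate")
})

test_that("standard errors round-trip through confidence intervals", {
  se <- 0.0732
  est <- exp(0.21)
  lo <- exp(0.21 - 1.959963984540054 * se)
  hi <- exp(0.21 + 1.959963984540054 * se)
  expect_equal(se_from_ci(lo, hi), se, tolerance = 1e-12)
})
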