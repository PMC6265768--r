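# Small configurations and panel builders shared across tests.

tiny_config <- function(...) {
  defaults <- list(n_areas = 1L, years = 2L, stations_per_area = 3L,
                   baseline_daily_deaths = 20, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Winter panel for one synthetic area, using the latent temperature series
# directly (compositing is tested separately).
sim_winter_panel <- function(config, beta = NULL, weights = NULL) {
  tt <- sim_temperature(config)
  dd <- sim_deaths(tt, config, weights = weights, beta = beta)
  panel <- tibble::tibble(
    date = dd$date,
    temp = tt$temp[!tt$pre_period],
    deaths = dd$deaths,
    mu = dd$mu
  )
  panel[is_winter(panel$date), ]
}

# A deterministic toy panel: one winter, arbitrary temperatures and counts.
toy_panel <- function(n_days = 151L, start = as.Date("2008-11-01"),
                      temp = NULL, deaths = NULL) {
  dates <- seq(start, by = "day", length.out = n_days)
  if (is.null(temp)) {
    # deterministic but aperiodic, so no design block is accidentally
    # collinear with a seasonal spline
    temp <- 5 + 4 * sin(seq_len(n_days) / 9) + 2 * sin(seq_len(n_days)^1.7)
  }
  tibble::tibble(
    date = dates,
    temp = temp,
    deaths = deaths %||% rep(10L, n_days)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
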