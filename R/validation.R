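#' Parameter-recovery study on synthetic single-area replicates
#'
#' Repeatedly simulates a single-area study with a known cumulative cold
#' effect and refits it end to end: temperature generation, winter panel,
#' threshold distributed-lag design, quasi-Poisson fit, and the cumulative
#' relative risk between the realised winter first percentile and maximum.
#' In each replicate the per-degree coefficient is set so the true RR
#' between those two temperatures equals `true_rr`, so bias and confidence
#' interval coverage can be read off directly.
#'
#' @param n_reps number of replicates.
#' @param seed base seed; replicate `i` uses `seed * 1000 + i`.
#' @param true_rr true cumulative relative risk between the winter first
#'   percentile and maximum temperature.
#' @param years,baseline_daily_deaths,overdispersion,lag_weight_shape
#'   generator settings (see [sim_config()]).
#' @param threshold cold threshold used for both generation and fitting.
#' @return tibble with one row per replicate: `log_rr`, `se`, `bias`
#'   (fitted minus true log RR), `covered` (true RR inside the 95% CI).
#' @export
recovery_study <- function(n_reps = 200L, seed = 1L, true_rr = 1.4,
                           years = 9L, baseline_daily_deaths = 30,
                           overdispersion = 1.5,
                           lag_weight_shape = "spline-bump",
                           threshold = 13) {
  purrr::map_dfr(seq_len(n_reps), function(i) {
    cfg <- sim_config(
      n_areas = 1L, years = years,
      baseline_daily_deaths = baseline_daily_deaths,
      overdispersion = overdispersion, lag_weight_shape = lag_weight_shape,
      cold_threshold = threshold, seed = seed * 1000L + i
    )
    tt <- sim_temperature(cfg)
    wt <- tt$temp[!tt$pre_period & is_winter(tt$date)]
    p1 <- unname(quantile(wt, 0.01, type = 7))
    tmax <- max(wt)
    span <- cold_excess(p1, threshold) - cold_excess(tmax, threshold)
    beta <- log(true_rr) / span
    dd <- sim_deaths(tt, cfg, beta = beta)
    panel <- tibble::tibble(date = dd$date,
                            temp = tt$temp[!tt$pre_period],
                            deaths = dd$deaths)
    panel <- panel[is_winter(panel$date), ]
    fit <- fit_quasipoisson(assemble_design(panel, threshold = threshold))
    est <- rr_between(fit, p1, tmax)
    tibble::tibble(
      log_rr = est$log_rr, se = est$se,
      bias = est$log_rr - log(true_rr),
      covered = est$lo <= true_rr && true_rr <= est$hi
    )
  })
}

#' Null-effect coverage study
#'
#' Simulates replicates with the cold effect switched off (`beta = 0`) and
#' checks how often the fitted cumulative relative risk's 95% interval
#' contains 1 -- a basic false-positive safety check of the whole chain.
#'
#' @inheritParams recovery_study
#' @return tibble with one row per replicate: `rr`, `lo`, `hi`,
#'   `contains_1`.
#' @export
null_coverage_study <- function(n_reps = 100L, seed = 1L, years = 5L,
                                baseline_daily_deaths = 30,
                                overdispersion = 1.5) {
  purrr::map_dfr(seq_len(n_reps), function(i) {
    cfg <- sim_config(
      n_areas = 1L, years = years,
      baseline_daily_deaths = baseline_daily_deaths,
      overdispersion = overdispersion, seed = seed * 1000L + 500L + i
    )
    tt <- sim_temperature(cfg)
    dd <- sim_deaths(tt, cfg, beta = 0)
    panel <- tibble::tibble(date = dd$date,
                            temp = tt$temp[!tt$pre_period],
                            deaths = dd$deaths)
    panel <- panel[is_winter(panel$date), ]
    fit <- fit_quasipoisson(assemble_design(panel,
                                            threshold = cfg$cold_threshold))
    wt <- panel$temp
    est <- rr_between(fit, unname(quantile(wt, 0.01, type = 7)), max(wt))
    tibble::tibble(rr = est$rr, lo = est$lo, hi = est$hi,
                   contains_1 = est$lo <= 1 && 1 <= est$hi)
  })
}

#' Planted unmet-need study
#'
#' Builds a nine-area synthetic study in which the cold effect of four
#' areas triples between the pre- and post-intervention periods while five
#' areas are unchanged, and fuel poverty is planted so that exactly two of
#' the worsened areas lie above the national value. Runs the full pipeline
#' and returns the estimated needs table alongside the planted truth, whose
#' `unmet_need` flags the worsened areas with above-national fuel poverty.
#'
#' @param seed integer seed for the generator.
#' @param national_fuel_poverty national comparator (%), default 11.04.
#' @return list with `needs` (pipeline output), `truth` (planted flags),
#'   and the full `pipeline` result.
#' @export
planted_needs_study <- function(seed = 1L, national_fuel_poverty = 11.04) {
  n_areas <- 9L
  raised <- 6:9                       # cold effect triples post-intervention
  fp <- c(8, 9, 9.5, 10, 10.5, 13, 14, 9, 10)
  cfg <- sim_config(n_areas = n_areas, years = 9L, stations_per_area = 4L,
                    baseline_daily_deaths = 30, seed = seed)
  beta_pre <- rep(cfg$cumulative_log_rr_per_degC, n_areas)
  beta_post <- beta_pre
  beta_post[raised] <- 3 * beta_pre[raised]
  w <- lag_weights(cfg$lag_weight_shape)
  cut <- as.Date("2011-07-01")        # splice date between the two regimes

  pieces <- purrr::map(seq_len(n_areas), function(a) {
    id <- sprintf("area%02d", a)
    tt <- sim_temperature(cfg, a)
    st <- sim_stations(tt, cfg, a)
    d_pre <- sim_deaths(tt, cfg, weights = w, beta = beta_pre[a],
                        area_index = a)
    d_post <- sim_deaths(tt, cfg, weights = w, beta = beta_post[a],
                         area_index = a)
    deaths <- dplyr::bind_rows(
      d_pre[d_pre$date < cut, c("date", "deaths")],
      d_post[d_post$date >= cut, c("date", "deaths")]
    )
    list(
      stations = dplyr::mutate(st, area_id = id, .before = 1),
      deaths = dplyr::mutate(deaths, area_id = id, .before = 1)
    )
  })
  stations <- dplyr::bind_rows(purrr::map(pieces, "stations"))
  deaths <- dplyr::bind_rows(purrr::map(pieces, "deaths"))
  fuel <- tibble::tibble(area_id = sprintf("area%02d", 1:n_areas),
                         fuel_poverty = fp)
  truth <- fuel |>
    dplyr::mutate(
      raised = dplyr::row_number() %in% raised,
      unmet_need = .data$raised & .data$fuel_poverty > national_fuel_poverty
    )
  res <- run_pipeline(stations, deaths, fuel_poverty = fuel,
                      national_fuel_poverty = national_fuel_poverty)
  list(needs = res$needs, truth = truth, pipeline = res)
}
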