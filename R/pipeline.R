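#' Run the full cold-mortality analysis pipeline
#'
#' Chains every stage for a multi-area study: per-area composite
#' temperature construction (coverage filter, anomaly averaging, seasonal
#' imputation), winter panel assembly, threshold distributed-lag
#' quasi-Poisson fits, cumulative relative risk between the winter first
#' percentile and maximum (plus the fixed 0 vs 13 C sensitivity contrast),
#' attributable burden, independent pre/post-period refits with the change
#' in risk, between-area heterogeneity per period, and -- when fuel-poverty
#' data are supplied -- the unmet-need classification.
#'
#' Period refits reuse the full-period threshold and contrast temperatures
#' so that pre-to-post changes reflect changes in the fitted association,
#' not shifts in each period's temperature distribution.
#'
#' @param stations tibble `area_id, station_id, date, temp`.
#' @param deaths tibble `area_id, date, deaths` (daily, all-year or winter).
#' @param fuel_poverty optional tibble `area_id, fuel_poverty` (%).
#' @param national_fuel_poverty national comparator (%), required for the
#'   needs classification; supplied as data, never recomputed from areas.
#' @param min_coverage station coverage filter, default 0.75.
#' @param threshold fixed cold threshold; default `NULL` = per-area winter
#'   maximum.
#' @param max_lag,lag_df,seasonal_df model settings (see
#'   [assemble_design()]).
#' @param cold_quantile quantile used as the cold comparison temperature,
#'   default 0.01.
#' @param pre_january,post_january period windows (see [split_periods()]).
#' @param out_dir optional directory; when given, every result table is
#'   written as CSV with a metadata header.
#' @param verbose print stage progress.
#' @return list of tibbles: `composites`, `temp_summaries`, `risk_table`,
#'   `period_risk`, `heterogeneity`, `needs` (or `NULL`), `log`, and the
#'   echoed `settings`.
#' @export
run_pipeline <- function(stations, deaths, fuel_poverty = NULL,
                         national_fuel_poverty = NULL,
                         min_coverage = 0.75, threshold = NULL,
                         max_lag = 28L, lag_df = 4L, seasonal_df = 4L,
                         cold_quantile = 0.01,
                         pre_january = 2007:2010, post_january = 2013:2015,
                         out_dir = NULL, verbose = FALSE) {
  areas <- sort(unique(deaths$area_id))
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    if (verbose) message(msg)
  }
  settings <- list(
    min_coverage = min_coverage, threshold = threshold %||% "area winter max",
    max_lag = max_lag, lag_df = lag_df, seasonal_df = seasonal_df,
    cold_quantile = cold_quantile,
    pre_january = pre_january, post_january = post_january
  )

  per_area <- purrr::map(areas, function(a) {
    st <- dplyr::filter(stations, .data$area_id == a)
    de <- dplyr::filter(deaths, .data$area_id == a)
    study_days <- seq(min(de$date), max(de$date), by = "day")
    n_st <- length(unique(st$station_id))
    comp <- build_composite(st, min_coverage = min_coverage,
                            study_days = study_days, area_id = a)
    say("%s: %d stations, composite built (%d days imputed)",
        a, n_st, sum(comp$imputed))
    summ <- summarize_temperature(comp, winter_only = TRUE)
    panel <- comp |>
      dplyr::filter(is_winter(.data$date)) |>
      dplyr::inner_join(de, by = c("area_id", "date")) |>
      dplyr::select("date", "temp", "deaths")
    h <- threshold %||% summ$highest
    t_from <- unname(quantile(panel$temp, cold_quantile, type = 7))
    t_ref <- max(panel$temp)

    dsn <- assemble_design(panel, threshold = h, max_lag = max_lag,
                           lag_df = lag_df, seasonal_df = seasonal_df)
    fit <- fit_quasipoisson(dsn)
    say("%s: fit on %d usable days (dispersion %.2f)", a, fit$n_obs,
        fit$dispersion)
    rr_full <- rr_between(fit, t_from, t_ref, period_label = "full")
    rr_sens <- rr_sensitivity_fixed(fit, period_label = "full")
    burden <- attributable_burden(fit, period_label = "full")

    periods <- split_periods(panel, pre_january, post_january)
    fit_period <- function(p, label) {
      d <- assemble_design(p, threshold = h, max_lag = max_lag,
                           lag_df = lag_df, seasonal_df = seasonal_df)
      f <- fit_quasipoisson(d)
      rr_between(f, t_from, t_ref, period_label = label)
    }
    rr_pre <- fit_period(periods$pre, "pre")
    rr_post <- fit_period(periods$post, "post")

    list(
      composite = comp,
      summary = dplyr::mutate(summ, area_id = a, .before = 1),
      risk = dplyr::bind_cols(
        tibble::tibble(area_id = a), rr_full,
        dplyr::rename_with(rr_sens[c("rr", "lo", "hi")],
                           ~ paste0(.x, "_0v13")),
        burden[c("attributable_number", "attributable_fraction",
                 "total_deaths")]
      ),
      period = dplyr::bind_rows(rr_pre, rr_post) |>
        dplyr::mutate(area_id = a, .before = 1)
    )
  })

  composites <- dplyr::bind_rows(purrr::map(per_area, "composite"))
  temp_summaries <- dplyr::bind_rows(purrr::map(per_area, "summary"))
  risk_table <- dplyr::bind_rows(purrr::map(per_area, "risk"))
  period_risk <- dplyr::bind_rows(purrr::map(per_area, "period"))

  het <- NULL
  if (length(areas) >= 2L) {
    het <- dplyr::bind_rows(
      period_risk[, c("period_label", "log_rr", "se")],
      risk_table[, c("period_label", "log_rr", "se")]
    ) |>
      dplyr::group_by(period = .data$period_label) |>
      dplyr::group_modify(~ i_squared(.x, "log_rr", "se")) |>
      dplyr::ungroup()
    say("heterogeneity: I2 pre %.1f%%, post %.1f%%",
        het$i_squared[het$period == "pre"],
        het$i_squared[het$period == "post"])
  } else {
    say("heterogeneity skipped: single area")
  }

  needs <- NULL
  if (!is.null(fuel_poverty)) {
    if (is.null(national_fuel_poverty)) {
      abort("national_fuel_poverty must be supplied with fuel_poverty data")
    }
    changes <- period_risk |>
      dplyr::select("area_id", "period_label", "rr") |>
      tidyr::pivot_wider(names_from = "period_label", values_from = "rr") |>
      dplyr::mutate(risk_change = risk_change(.data$pre, .data$post)) |>
      dplyr::inner_join(fuel_poverty, by = "area_id")
    needs <- classify_need(changes, national_fuel_poverty)
    say("needs: %d of %d areas flagged with unmet need",
        sum(needs$unmet_need), nrow(needs))
  }

  log_tbl <- tibble::tibble(message = log_lines)
  out <- list(composites = composites, temp_summaries = temp_summaries,
              risk_table = risk_table, period_risk = period_risk,
              heterogeneity = het, needs = needs, log = log_tbl,
              settings = settings)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    meta <- c(
      sprintf("max_lag: %d", max_lag), sprintf("lag_df: %d", lag_df),
      sprintf("seasonal_df: %d", seasonal_df),
      sprintf("threshold: %s", paste(settings$threshold, collapse = " ")),
      sprintf("cold_quantile: %g", cold_quantile)
    )
    for (nm in c("temp_summaries", "risk_table", "period_risk",
                 "heterogeneity", "needs", "log")) {
      if (!is.null(out[[nm]])) {
        write_output_table(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                           meta)
      }
    }
  }
  out
}
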