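#' Station coverage over a study period
#'
#' Coverage is the fraction of study days on which a station reports a
#' non-missing temperature. Missing station-days may be encoded either as
#' absent rows or as `NA` temperatures; both count as missing.
#'
#' @param stations tibble with columns `station_id`, `date`, `temp` (one
#'   area's stations).
#' @param study_days vector of all calendar days in the study; defaults to
#'   the full range of dates present.
#' @return tibble with `station_id`, `n_obs`, `coverage`, ordered as first
#'   encountered.
#' @export
station_coverage <- function(stations, study_days = NULL) {
  study_days <- study_days %||%
    seq(min(stations$date), max(stations$date), by = "day")
  stations |>
    dplyr::filter(!is.na(.data$temp), .data$date %in% study_days) |>
    dplyr::distinct(.data$station_id, .data$date) |>
    dplyr::count(.data$station_id, name = "n_obs") |>
    dplyr::right_join(
      tibble::tibble(station_id = unique(stations$station_id)),
      by = "station_id"
    ) |>
    dplyr::mutate(
      n_obs = dplyr::coalesce(.data$n_obs, 0L),
      coverage = .data$n_obs / length(study_days)
    )
}

#' Drop stations below a minimum coverage
#'
#' Retains exactly the stations whose coverage over the study period is at
#' least `min_coverage` (default 75%), preserving input order. An area left
#' with no stations is an error naming the area, because a composite cannot
#' be formed for it.
#'
#' @inheritParams station_coverage
#' @param min_coverage required fraction of study days, in `(0, 1]`.
#' @param area_id label used in error messages.
#' @return the retained rows of `stations`.
#' @export
coverage_filter <- function(stations, min_coverage = 0.75, study_days = NULL,
                            area_id = "area") {
  stopifnot(min_coverage > 0, min_coverage <= 1)
  cov <- station_coverage(stations, study_days)
  keep <- cov$station_id[cov$coverage >= min_coverage]
  if (length(keep) == 0L) {
    abort(sprintf(
      "no station in %s reaches %.0f%% coverage (best: %.1f%%)",
      area_id, 100 * min_coverage, 100 * max(cov$coverage)
    ))
  }
  dplyr::filter(stations, .data$station_id %in% keep)
}

#' Composite area temperature from multiple stations
#'
#' Combines station series into one daily area series. Stations are first
#' standardised to anomalies by subtracting each station's mean computed
#' over days it shares with at least one other station (all its days when it
#' is alone); anomalies are averaged across the stations reporting each day
#' and the result re-centred to the pooled mean of all observations. This
#' prevents a systematically cold (or warm) station's missingness pattern
#' from biasing the composite level. Days with no reporting station remain
#' missing (`NA`), to be filled by [impute_missing()].
#'
#' @inheritParams station_coverage
#' @param area_id label attached to the output.
#' @return tibble with `area_id`, `date`, `temp`, `n_stations` (per-day
#'   count of contributing stations), covering every study day.
#' @export
composite_mean <- function(stations, study_days = NULL, area_id = "area") {
  stopifnot(nrow(stations) > 0)
  study_days <- study_days %||%
    seq(min(stations$date), max(stations$date), by = "day")
  obs <- dplyr::filter(stations, !is.na(.data$temp))
  per_day_n <- dplyr::count(obs, .data$date, name = "n_stations")
  shared_days <- per_day_n$date[per_day_n$n_stations >= 2L]
  st_means <- obs |>
    dplyr::group_by(.data$station_id) |>
    dplyr::summarise(
      m = if (any(.data$date %in% shared_days)) {
        mean(.data$temp[.data$date %in% shared_days])
      } else mean(.data$temp),
      .groups = "drop"
    )
  pooled_mean <- mean(obs$temp)
  daily <- obs |>
    dplyr::left_join(st_means, by = "station_id") |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(
      anom = mean(.data$temp - .data$m),
      n_stations = dplyr::n(),
      .groups = "drop"
    )
  tibble::tibble(area_id = area_id, date = study_days) |>
    dplyr::left_join(daily, by = "date") |>
    dplyr::mutate(
      temp = .data$anom + pooled_mean,
      n_stations = dplyr::coalesce(.data$n_stations, 0L)
    ) |>
    dplyr::select("area_id", "date", "temp", "n_stations")
}

#' Fill missing days of a composite series
#'
#' Gaps are filled by a seasonal regression prediction -- a natural cubic
#' spline on day of year fit to the observed days -- plus linear
#' interpolation of the observed residuals across interior gaps (gaps at the
#' series edges take the seasonal prediction alone). Observed days are never
#' altered. The series must already be mostly complete (`min_frac`, default
#' 90% non-missing) and no gap may exceed `max_gap` days; beyond that the
#' seasonal model cannot be trusted to reconstruct weather and the function
#' fails rather than fabricate it.
#'
#' @param composite tibble from [composite_mean()] (needs `date`, `temp`).
#' @param seasonal_df spline degrees of freedom for the day-of-year fit.
#' @param max_gap longest permissible run of consecutive missing days.
#' @param min_frac minimum fraction of non-missing days required.
#' @return `composite` with `temp` complete and a logical `imputed` column.
#' @export
impute_missing <- function(composite, seasonal_df = 6, max_gap = 30,
                           min_frac = 0.9) {
  miss <- is.na(composite$temp)
  if (!any(miss)) {
    return(dplyr::mutate(composite, imputed = FALSE))
  }
  if (mean(!miss) < min_frac) {
    abort(sprintf("only %.1f%% of days observed; need >= %.0f%% to impute",
                  100 * mean(!miss), 100 * min_frac))
  }
  gap <- longest_run(miss)
  if (gap > max_gap) {
    abort(sprintf("longest gap is %d days, exceeding max_gap = %d", gap, max_gap))
  }
  doy <- day_of_year(composite$date)
  obs <- which(!miss)
  basis_obs <- splines::ns(doy[obs], df = seasonal_df)
  fit <- lm(composite$temp[obs] ~ basis_obs)
  seas <- drop(cbind(1, predict(basis_obs, doy)) %*% coef(fit))
  resid_obs <- composite$temp[obs] - seas[obs]
  idx <- seq_len(nrow(composite))
  r_interp <- approx(obs, resid_obs, xout = idx, rule = 1)$y
  r_interp[is.na(r_interp)] <- 0        # edge gaps: seasonal prediction only
  out <- composite
  out$temp[miss] <- seas[miss] + r_interp[miss]
  dplyr::mutate(out, imputed = miss)
}

#' Temperature distribution summaries
#'
#' The lowest, first-percentile, median and highest daily mean temperatures
#' of a complete composite series, optionally restricted to winter months
#' (November--March), the period over which cold-mortality models are fit.
#' Quantiles use linear interpolation between order statistics (type 7),
#' which the reported first-percentile values depend on.
#'
#' @param composite complete series with `date` and `temp`.
#' @param winter_only restrict to November--March (default `TRUE`).
#' @return one-row tibble: `lowest`, `p1`, `median`, `highest`.
#' @export
summarize_temperature <- function(composite, winter_only = TRUE) {
  x <- composite$temp
  if (winter_only) x <- x[is_winter(composite$date)]
  if (length(x) == 0L) abort("no winter days in series; cannot summarise")
  if (anyNA(x)) abort("series has missing values; impute first")
  q <- quantile(x, c(0, 0.01, 0.5, 1), type = 7, names = FALSE)
  tibble::tibble(lowest = q[1], p1 = q[2], median = q[3], highest = q[4])
}

#' Build one area's composite temperature series end to end
#'
#' Convenience chain: coverage filter, anomaly-standardised composite mean,
#' seasonal imputation. Fails (naming the area) if no station passes the
#' coverage filter.
#'
#' @inheritParams coverage_filter
#' @inheritParams impute_missing
#' @return complete composite tibble (see [impute_missing()]).
#' @export
build_composite <- function(stations, min_coverage = 0.75, study_days = NULL,
                            area_id = "area", seasonal_df = 6, max_gap = 30,
                            min_frac = 0.9) {
  stations |>
    coverage_filter(min_coverage, study_days, area_id) |>
    composite_mean(study_days, area_id) |>
    impute_missing(seasonal_df, max_gap, min_frac)
}
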