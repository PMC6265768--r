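#' Between-area heterogeneity: Cochran's Q and I-squared
#'
#' Inverse-variance weights `w_i = 1/se_i^2` give the pooled mean
#' `theta_bar = sum(w theta)/sum(w)`, `Q = sum(w (theta - theta_bar)^2)`
#' on `k - 1` degrees of freedom, and
#' `I2 = max(0, 100 (Q - (k - 1)) / Q)` -- the percentage of between-area
#' variation in log relative risk beyond what sampling error explains.
#'
#' @param data data frame of area estimates (the national row, if any,
#'   must be excluded by the caller).
#' @param log_rr,se columns (tidy-eval) holding the log relative risks and
#'   their standard errors.
#' @return one-row tibble: `Q`, `df`, `i_squared` (%).
#' @examples
#' i_squared(data.frame(b = c(0.1, 0.3), s = c(0.1, 0.1)), b, s)  # I2 = 50
#' @export
i_squared <- function(data, log_rr, se) {
  theta <- dplyr::pull(data, {{ log_rr }})
  s <- dplyr::pull(data, {{ se }})
  k <- length(theta)
  if (k < 2L) abort("need at least 2 areas for a heterogeneity statistic")
  if (any(s <= 0)) abort("all standard errors must be positive")
  w <- 1 / s^2
  theta_bar <- sum(w * theta) / sum(w)
  Q <- sum(w * (theta - theta_bar)^2)
  i2 <- if (Q > 0) max(0, 100 * (Q - (k - 1)) / Q) else 0
  tibble::tibble(Q = Q, df = k - 1L, i_squared = i2)
}

#' Change in log relative risk between two periods
#'
#' `log(rr_post) - log(rr_pre)`: positive values mean risk worsened after
#' the intervention.
#'
#' @param rr_pre,rr_post relative risks (vectors align by position).
#' @return numeric change(s) in log RR.
#' @examples
#' risk_change(1.35, 2.35)  # steepest observed incline, about 0.554
#' @export
risk_change <- function(rr_pre, rr_post) {
  log(rr_post) - log(rr_pre)
}

#' Classify areas with unmet need
#'
#' An area has unmet need when BOTH hold: its pre-to-post change in risk is
#' strictly worse than the median area's change, and its fuel-poverty
#' percentage is strictly above the national value. Areas exactly at the
#' median (or at the national fuel-poverty level) are not flagged.
#'
#' @param data data frame with one row per area, columns `area_id`,
#'   `risk_change` (log-RR difference, post minus pre) and `fuel_poverty`
#'   (% of households).
#' @param national_fuel_poverty the national fuel-poverty comparator (%),
#'   supplied as data (not recomputed as a mean of areas).
#' @return `data` with logical columns `exceeds_median_change`,
#'   `fuel_poverty_above_national`, `unmet_need` appended.
#' @export
classify_need <- function(data, national_fuel_poverty) {
  stopifnot(all(c("area_id", "risk_change", "fuel_poverty") %in% names(data)))
  med <- median(data$risk_change)
  data |>
    dplyr::mutate(
      exceeds_median_change = .data$risk_change > med,
      fuel_poverty_above_national = .data$fuel_poverty > national_fuel_poverty,
      unmet_need = .data$exceeds_median_change & .data$fuel_poverty_above_national
    )
}

#' Areas whose risk is significantly above the national estimate
#'
#' Two criteria are offered. `"ci"` (default) counts areas whose CI lower
#' bound exceeds the national CI upper bound (non-overlap). `"z"` runs a
#' two-sample z-test of each area against the national estimate via
#' [compare_rr()] and counts areas significantly higher at `alpha`.
#'
#' @param data area estimate table with columns `rr`, `lo`, `hi` and a
#'   logical `is_national` column flagging exactly one national row (which
#'   is excluded from the area side of the comparison).
#' @param method `"ci"` or `"z"`.
#' @param alpha significance level for the z method.
#' @return integer count of areas above the national estimate.
#' @export
count_exceeding_national <- function(data, method = c("ci", "z"), alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(all(c("rr", "lo", "hi", "is_national") %in% names(data)))
  if (sum(data$is_national) != 1L) {
    abort("table must contain exactly one national row (is_national == TRUE)")
  }
  nat <- dplyr::filter(data, .data$is_national)
  areas <- dplyr::filter(data, !.data$is_national)
  if (method == "ci") {
    sum(areas$lo > nat$hi)
  } else {
    above <- purrr::map_lgl(seq_len(nrow(areas)), function(i) {
      cmp <- compare_rr(areas[i, ], nat, alpha = alpha)
      cmp$significant && areas$rr[i] > nat$rr
    })
    sum(above)
  }
}
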