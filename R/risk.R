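#' Cumulative relative risk between two temperatures
#'
#' The lag-cumulative relative risk of death at `t_from` relative to
#' `t_ref`, typically the winter first-percentile temperature against the
#' maximum (the threshold, where risk is null). The contrast sums the
#' change in cold excess over every lag: with lag basis `B` and cold
#' coefficients `beta_c`, the log RR is
#' `(z(t_from) - z(t_ref)) * colSums(B) . beta_c`, and the 95% interval is
#' Wald on the log scale, hence symmetric in `log(rr)`.
#'
#' @param fit a `qp_fit` carrying its `threshold_dlm_design`.
#' @param t_from colder comparison temperature, degrees C.
#' @param t_ref reference temperature (must exceed `t_from`).
#' @param level confidence level, default 0.95.
#' @param period_label,stratum optional labels carried into the output.
#' @return one-row tibble: `t_from`, `t_ref`, `log_rr`, `se`, `rr`, `lo`,
#'   `hi`, plus any labels.
#' @export
rr_between <- function(fit, t_from, t_ref, level = 0.95,
                       period_label = NULL, stratum = NULL) {
  stopifnot(inherits(fit, "qp_fit"))
  dsn <- fit$design
  if (is.null(dsn)) abort("fit carries no design; refit from assemble_design()")
  if (t_from >= t_ref) abort("t_from must be colder than t_ref")
  if (!fit$converged) warn("fit did not converge; risk estimate is unreliable")
  dz <- cold_excess(t_from, dsn$h) - cold_excess(t_ref, dsn$h)
  contrast <- numeric(length(fit$beta))
  contrast[dsn$blocks$cold] <- dz * colSums(dsn$B)
  lc <- linear_combination(fit, contrast)
  zq <- qnorm(1 - (1 - level) / 2)
  out <- tibble::tibble(
    t_from = t_from, t_ref = t_ref,
    log_rr = lc$estimate, se = lc$se,
    rr = exp(lc$estimate),
    lo = exp(lc$estimate - zq * lc$se),
    hi = exp(lc$estimate + zq * lc$se)
  )
  if (!is.null(period_label)) out$period_label <- period_label
  if (!is.null(stratum)) out$stratum <- stratum
  out
}

#' Relative risk at the common 0 vs 13 degree contrast
#'
#' Sensitivity analysis on a contrast shared by every area -- 0 C (around
#' maximum mortality) against 13 C (around minimum mortality) -- so that
#' between-area comparisons do not depend on each area's own temperature
#' distribution. Delegates to [rr_between()].
#'
#' @inheritParams rr_between
#' @export
rr_sensitivity_fixed <- function(fit, level = 0.95, period_label = NULL,
                                 stratum = NULL) {
  rr_between(fit, 0, 13, level = level, period_label = period_label,
             stratum = stratum)
}

#' Deaths attributable to cold
#'
#' Backward attribution: each day's deaths are attributed to the cold excess
#' it experienced over the previous `max_lag` days. With lag-resolved
#' coefficients `eta = B beta_c`, day `t` carries cumulative log effect
#' `a_t = sum_l eta_l z_{t-l}`, attributable fraction `1 - exp(-a_t)`, and
#' attributable deaths `(1 - exp(-a_t)) y_t`; these are summed over the
#' usable winter days. The counterfactual is the threshold temperature,
#' where the cold effect vanishes.
#'
#' @param fit a `qp_fit` carrying its design.
#' @param period_label optional label.
#' @return one-row tibble: `attributable_number`, `attributable_fraction`
#'   (% of winter deaths), `total_deaths`, plus the label.
#' @export
attributable_burden <- function(fit, period_label = NULL) {
  stopifnot(inherits(fit, "qp_fit"))
  dsn <- fit$design
  if (is.null(dsn)) abort("fit carries no design; refit from assemble_design()")
  eta <- drop(dsn$B %*% fit$beta[dsn$blocks$cold])
  a <- drop(dsn$lagged %*% eta)
  af <- 1 - exp(-a)
  y <- dsn$y
  an <- sum(af * y)
  out <- tibble::tibble(
    attributable_number = an,
    attributable_fraction = 100 * an / sum(y),
    total_deaths = sum(y)
  )
  if (!is.null(period_label)) out$period_label <- period_label
  out
}

#' Split a winter panel into pre- and post-intervention periods
#'
#' Winters (labelled by the year of their January) are assigned whole to a
#' period; the default windows are January 2007--2010 for the
#' pre-intervention period and January 2013--2015 for the post period, so
#' the 2010/11 and 2011/12 transition winters around the intervention's
#' introduction belong to neither. Each returned panel is refit
#' independently.
#'
#' @param panel winter panel with a `date` column (a `winter` column is
#'   derived if absent).
#' @param pre_january,post_january January years defining each period.
#' @return list of two tibbles, `pre` and `post`.
#' @export
split_periods <- function(panel, pre_january = 2007:2010,
                          post_january = 2013:2015) {
  if (length(intersect(pre_january, post_january)) > 0) {
    abort("pre and post windows overlap")
  }
  if (!"winter" %in% names(panel)) {
    panel <- dplyr::mutate(panel, winter = winter_label(.data$date))
  }
  pre <- dplyr::filter(panel, .data$winter %in% pre_january)
  post <- dplyr::filter(panel, .data$winter %in% post_january)
  if (nrow(pre) == 0L) abort("pre period is empty")
  if (nrow(post) == 0L) abort("post period is empty")
  list(pre = pre, post = post)
}

#' Standard error of a log relative risk from its confidence interval
#'
#' Inverts the Wald construction: `se = (log(hi) - log(lo)) / (2 * 1.96)`
#' for a 95% interval.
#'
#' @param lo,hi interval bounds on the RR scale.
#' @param level confidence level the interval was built at.
#' @return numeric standard error(s).
#' @export
se_from_ci <- function(lo, hi, level = 0.95) {
  zq <- qnorm(1 - (1 - level) / 2)
  (log(hi) - log(lo)) / (2 * zq)
}

#' Compare two independent relative-risk estimates
#'
#' Two-sample z-test on the log scale with standard errors recovered from
#' the confidence intervals:
#' `z = (log(rr1) - log(rr2)) / sqrt(se1^2 + se2^2)`, two-sided normal
#' p-value, significance at `alpha` (default 0.05).
#'
#' @param est1,est2 one-row tibbles with `rr`, `lo`, `hi` (as returned by
#'   [rr_between()]).
#' @param alpha two-sided significance level.
#' @return one-row tibble: `z`, `p_value`, `significant`.
#' @export
compare_rr <- function(est1, est2, alpha = 0.05) {
  se1 <- se_from_ci(est1$lo, est1$hi)
  se2 <- se_from_ci(est2$lo, est2$hi)
  if (se1 <= 0 || se2 <= 0) abort("degenerate confidence interval (hi <= lo)")
  z <- (log(est1$rr) - log(est2$rr)) / sqrt(se1^2 + se2^2)
  p <- 2 * pnorm(-abs(z))
  tibble::tibble(z = z, p_value = p, significant = p < alpha)
}
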