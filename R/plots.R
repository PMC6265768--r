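#' Plot the cumulative exposure-response curve
#'
#' Cumulative (lags 0 to `max_lag`) relative risk across a grid of
#' temperatures, relative to the threshold where the cold effect is null,
#' with a pointwise 95% band. Above the threshold the curve is flat at 1 by
#' construction.
#'
#' @param fit a `qp_fit` carrying its design.
#' @param n_grid number of grid points across the panel temperature range.
#' @return a ggplot object.
#' @export
plot_exposure_response <- function(fit, n_grid = 80L) {
  stopifnot(inherits(fit, "qp_fit"))
  dsn <- fit$design
  temps <- seq(min(dsn$panel$temp), max(dsn$panel$temp), length.out = n_grid)
  curve <- purrr::map_dfr(temps, function(t) {
    if (t >= dsn$h) {
      tibble::tibble(temp = t, rr = 1, lo = 1, hi = 1)
    } else {
      est <- rr_between(fit, t, dsn$h)
      tibble::tibble(temp = t, rr = est$rr, lo = est$lo, hi = est$hi)
    }
  })
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$temp, y = .data$rr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "Daily mean temperature (°C)",
                  y = "Cumulative relative risk (lags 0-28)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_exposure_response
#' @param object,... autoplot method arguments.
#' @export
autoplot.qp_fit <- function(object, ...) {
  plot_exposure_response(object, ...)
}

#' Plot pre/post-period relative risks with intervals
#'
#' Error-bar comparison of the cumulative relative risk by area between the
#' pre- and post-intervention periods.
#'
#' @param period_risk tibble with `area_id`, `period_label`, `rr`, `lo`,
#'   `hi` (the `period_risk` element of [run_pipeline()] output).
#' @return a ggplot object.
#' @export
plot_period_comparison <- function(period_risk) {
  ggplot2::ggplot(
    period_risk,
    ggplot2::aes(x = .data$area_id, y = .data$rr,
                 colour = .data$period_label)
  ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Cumulative relative risk",
                  colour = "Period") +
    ggplot2::theme_minimal()
}

#' Plot a lag-weight or lag-coefficient profile
#'
#' Lag-resolved log relative risk per degree of cold excess implied by a
#' fit (`B %*% beta_cold`), useful for checking how the spline lag basis
#' distributes the cumulative effect.
#'
#' @param fit a `qp_fit` carrying its design.
#' @return a ggplot object.
#' @export
plot_lag_profile <- function(fit) {
  stopifnot(inherits(fit, "qp_fit"))
  dsn <- fit$design
  eta <- drop(dsn$B %*% fit$beta[dsn$blocks$cold])
  df <- tibble::tibble(lag = 0:dsn$max_lag, eta = eta)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag, y = .data$eta)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Lag (days)",
                  y = "Log RR per °C cold excess") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
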