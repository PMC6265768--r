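#' Cold excess below a threshold
#'
#' Degrees below the cold threshold `h`: `max(0, h - temp)`. The threshold
#' distributed-lag model assumes mortality risk is null above `h` and
#' log-linear in this quantity below it.
#'
#' @param temp temperature(s), degrees C.
#' @param threshold the cold threshold `h`, degrees C.
#' @return nonnegative numeric vector.
#' @examples
#' cold_excess(c(14.3, -2.97), 14.3)
#' @export
cold_excess <- function(temp, threshold) {
  pmax(0, threshold - temp)
}

#' Natural cubic spline basis
#'
#' Thin wrapper around [splines::ns()] returning a plain matrix with `df`
#' columns, linear beyond the boundary knots. Used for the seasonal
#' (day-of-year), long-term trend, and lag dimensions of the model.
#'
#' @param x numeric vector.
#' @param df degrees of freedom (columns); must not exceed the number of
#'   distinct `x` values.
#' @param boundary_knots length-2 boundary; defaults to `range(x)`.
#' @param knots optional interior knots (overrides `df`-based placement).
#' @param intercept include the constant function in the span (used for the
#'   lag basis, where the flat profile must be representable).
#' @return matrix with `length(x)` rows.
#' @export
natural_cubic_basis <- function(x, df, boundary_knots = range(x),
                                knots = NULL, intercept = FALSE) {
  stopifnot(df >= 1, all(is.finite(x)))
  if (df > length(unique(x))) {
    abort(sprintf("df = %d exceeds the %d distinct x values", df,
                  length(unique(x))))
  }
  b <- if (is.null(knots)) {
    splines::ns(x, df = df, Boundary.knots = boundary_knots,
                intercept = intercept)
  } else {
    splines::ns(x, knots = knots, Boundary.knots = boundary_knots,
                intercept = intercept)
  }
  unname(b[, , drop = FALSE])
}

#' Basis over the lag dimension
#'
#' Returns the matrix `B` (`max_lag + 1` rows, one per lag) whose columns
#' are the lag-basis functions. `"spline"` (the default) is a natural cubic
#' spline with `df` columns, intercept included so constant lag profiles are
#' representable, and interior knots equally spaced on the log-lag scale --
#' lag effects change fastest at short lags. `"identity"` gives one column
#' per lag (unconstrained profile; used by exact oracles), `"uniform"` one
#' constant column (cumulative-only model).
#'
#' @param max_lag largest lag, default 28.
#' @param type `"spline"`, `"identity"`, or `"uniform"`.
#' @param df columns of the spline basis (>= 2).
#' @return matrix with `max_lag + 1` rows.
#' @export
lag_basis_matrix <- function(max_lag = 28L, type = c("spline", "identity", "uniform"),
                             df = 4L) {
  type <- match.arg(type)
  l <- 0:max_lag
  switch(type,
    "identity" = diag(max_lag + 1L),
    "uniform"  = matrix(1, max_lag + 1L, 1L),
    "spline"   = {
      stopifnot(df >= 2)
      nk <- df - 2L  # ns with intercept: df = n_knots + 2
      knots <- if (nk > 0) {
        10^(seq(log10(1), log10(max_lag), length.out = nk + 2L))[2:(nk + 1L)]
      } else NULL
      natural_cubic_basis(l, df = df, boundary_knots = c(0, max_lag),
                          knots = knots, intercept = TRUE)
    }
  )
}

#' Distributed-lag block of cold excess
#'
#' For each day `t` with a complete lag history inside its own winter group,
#' column `j` of the block is `sum_l B[l+1, j] * z[t-l]` where `z` is the
#' cold-excess series and `B` the lag basis. Lag windows never cross group
#' boundaries: the first `max_lag` days of each winter are excluded from the
#' usable rows, mirroring the treatment of winters as multiple independent
#' series.
#'
#' @param z cold-excess series aligned with `groups`.
#' @param groups group (winter) label per element of `z`; must be constant
#'   on runs (each group contiguous).
#' @param B lag-basis matrix from [lag_basis_matrix()].
#' @return list with `block` (matrix, one row per usable day), `usable`
#'   (integer indices into `z`), and `lagged` (the raw `max_lag + 1`-column
#'   lagged-exposure matrix on usable rows, lag 0 first).
#' @export
build_lag_block <- function(z, groups, B) {
  stopifnot(length(z) == length(groups))
  L <- nrow(B) - 1L
  r <- rle(as.character(groups))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  too_short <- r$lengths < L + 1L
  if (any(too_short)) {
    abort(sprintf("group(s) %s shorter than max_lag + 1 = %d days",
                  paste(r$values[too_short], collapse = ", "), L + 1L))
  }
  pieces <- purrr::map(seq_along(starts), function(g) {
    idx <- starts[g]:ends[g]
    Zl <- stats::embed(z[idx], L + 1L)  # cols: lag 0 .. L
    list(lagged = Zl, usable = idx[(L + 1L):length(idx)])
  })
  lagged <- do.call(rbind, purrr::map(pieces, "lagged"))
  usable <- unlist(purrr::map(pieces, "usable"))
  list(block = lagged %*% B, usable = usable, lagged = lagged)
}

#' Assemble the threshold distributed-lag design
#'
#' Builds the full model design for one area's winter panel: the cold-excess
#' lag block, a natural cubic spline on day-within-winter (seasonal
#' variation), a natural cubic spline on calendar time (long-term trend,
#' about one df per year, omitted when only one winter is present), six
#' day-of-week indicators (Sunday absorbed in the intercept), and the
#' intercept. Rows are the panel days with a complete lag history inside
#' their winter.
#'
#' @param panel tibble with `date`, `temp`, `deaths` covering winter days;
#'   a `winter` column is derived with [winter_label()] if absent.
#' @param threshold cold threshold `h`; default `NULL` uses the panel's
#'   maximum temperature (risk null above the warmest observed day),
#'   override with a fixed value (e.g. 13) for sensitivity analyses.
#' @param max_lag lag window length, default 28 days.
#' @param lag_type,lag_df lag basis (see [lag_basis_matrix()]).
#' @param seasonal_df df of the day-within-winter spline, default 4.
#' @param trend_df df of the calendar-time spline; default one per winter.
#' @return object of class `threshold_dlm_design`: list with the model
#'   matrix `X` (usable rows), response `y`, `usable` indices, `panel`,
#'   threshold `h`, `max_lag`, lag basis `B`, `lagged` exposures, and the
#'   column index of each block in `blocks`.
#' @export
assemble_design <- function(panel, threshold = NULL, max_lag = 28L,
                            lag_type = c("spline", "identity", "uniform"),
                            lag_df = 4L, seasonal_df = 4L, trend_df = NULL) {
  lag_type <- match.arg(lag_type)
  stopifnot(all(c("date", "temp", "deaths") %in% names(panel)))
  if (anyNA(panel$temp)) abort("panel temperature has missing values")
  if (!"winter" %in% names(panel)) {
    panel <- dplyr::mutate(panel, winter = winter_label(.data$date))
  }
  if (anyNA(panel$winter)) abort("panel contains non-winter days")
  panel <- dplyr::arrange(panel, .data$date)
  h <- threshold %||% max(panel$temp)
  B <- lag_basis_matrix(max_lag, lag_type, lag_df)
  z <- cold_excess(panel$temp, h)
  lag <- build_lag_block(z, panel$winter, B)
  u <- lag$usable
  n_winters <- length(unique(panel$winter))

  wstart <- as.Date(sprintf("%d-11-01", panel$winter - 1L))
  wdoy <- as.numeric(panel$date - wstart)      # days since 1 Nov of the season
  seasonal <- natural_cubic_basis(wdoy, df = seasonal_df)
  tnum <- as.numeric(panel$date - min(panel$date))
  trend_df <- trend_df %||% (if (n_winters > 1L) n_winters else 0L)
  trend <- if (trend_df >= 1L) {
    natural_cubic_basis(tnum, df = trend_df)
  } else NULL
  wd <- factor(as.POSIXlt(panel$date)$wday, levels = 0:6,
               labels = c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat"))
  dow <- stats::model.matrix(~wd)[, -1, drop = FALSE]

  blocks_full <- list(
    intercept = matrix(1, nrow(panel), 1, dimnames = list(NULL, "(Intercept)")),
    cold = `colnames<-`(matrix(NA_real_, nrow(panel), ncol(B)),
                        paste0("cold", seq_len(ncol(B)))),
    seasonal = `colnames<-`(seasonal, paste0("season", seq_len(ncol(seasonal)))),
    trend = if (!is.null(trend)) {
      `colnames<-`(trend, paste0("trend", seq_len(ncol(trend))))
    },
    dow = dow
  )
  blocks_full$cold[u, ] <- lag$block
  blocks_full <- purrr::compact(blocks_full)
  X <- do.call(cbind, purrr::map(blocks_full, ~ .x[u, , drop = FALSE]))
  col_of <- split(seq_len(ncol(X)),
                  rep(names(blocks_full), purrr::map_int(blocks_full, ncol)))

  # locate any rank deficiency by adding blocks one at a time
  acc <- NULL
  for (bn in names(blocks_full)) {
    acc <- cbind(acc, blocks_full[[bn]][u, , drop = FALSE])
    if (qr(acc)$rank < ncol(acc)) {
      abort(sprintf("design is rank deficient after adding the '%s' block", bn))
    }
  }

  structure(list(
    X = X, y = panel$deaths[u], usable = u, panel = panel,
    h = h, max_lag = max_lag, lag_type = lag_type, B = B,
    lagged = lag$lagged, blocks = col_of,
    seasonal_df = seasonal_df, trend_df = trend_df
  ), class = "threshold_dlm_design")
}

#' @export
print.threshold_dlm_design <- function(x, ...) {
  cat(sprintf(
    "<threshold_dlm_design> %d usable days (of %d), threshold %.2f C, lags 0-%d (%s basis, %d col)\n",
    nrow(x$X), nrow(x$panel), x$h, x$max_lag, x$lag_type, ncol(x$B)
  ))
  invisible(x)
}
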