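#' Quasi-Poisson regression by iteratively reweighted least squares
#'
#' Fits a log-link count regression whose point estimates coincide with the
#' Poisson maximum likelihood and whose covariance is inflated by the
#' Pearson overdispersion, `vcov = phi * (X'WX)^{-1}` with
#' `phi = Pearson chi-square / residual df`. Starting values are zero except
#' the intercept at `log(mean(y) + 0.5)`; convergence is declared when the
#' relative deviance change falls below `tol` (default 1e-9) within `maxit`
#' iterations. Days with zero deaths are ordinary observations -- the log
#' link constrains the mean, not the data.
#'
#' @param design a `threshold_dlm_design` from [assemble_design()], or a
#'   numeric response vector `y` (then `X` must be given).
#' @param X model matrix when `design` is a plain response vector.
#' @param tol relative deviance convergence tolerance.
#' @param maxit maximum IRLS iterations.
#' @return object of class `qp_fit`: `beta`, `vcov`, `dispersion`,
#'   `deviance`, `n_obs`, `df_resid`, `converged`, `iter`, `fitted`, and the
#'   originating `design` (when one was supplied).
#' @export
fit_quasipoisson <- function(design, X = NULL, tol = 1e-9, maxit = 100L) {
  if (inherits(design, "threshold_dlm_design")) {
    y <- design$y
    X <- design$X
    dsn <- design
  } else {
    y <- design
    if (is.null(X)) abort("supply a design object, or y together with X")
    X <- as.matrix(X)
    dsn <- NULL
  }
  if (any(y < 0) || any(y != floor(y))) {
    abort("response must be nonnegative integer counts")
  }
  n <- length(y)
  p <- ncol(X)
  if (n <= p) abort("more columns than observations")
  if (qr(X)$rank < p) abort("design matrix is rank deficient")

  beta <- numeric(p)
  int <- which(colnames(X) == "(Intercept)")
  if (length(int) == 0L) int <- which(apply(X, 2, function(c) all(c == 1)))[1]
  if (!is.na(int[1])) beta[int[1]] <- log(mean(y) + 0.5)

  dev_of <- function(mu) {
    2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  }
  dev_old <- Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- pmin(drop(X %*% beta), 30)   # guard against overflow early on
    mu <- exp(eta)
    w <- mu
    zwork <- eta + (y - mu) / mu
    beta_new <- unname(stats::lm.wfit(X, zwork, w)$coefficients)
    if (anyNA(beta_new)) abort("IRLS hit a singular weighted system")
    beta <- beta_new
    mu <- exp(pmin(drop(X %*% beta), 30))
    dev <- dev_of(mu)
    if (is.finite(dev_old) && abs(dev - dev_old) / (abs(dev) + 0.1) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= maxit) break
    dev_old <- dev
  }
  if (!converged) {
    warn(sprintf("IRLS did not converge in %d iterations", maxit))
  }
  w <- mu
  XtWX <- crossprod(X * sqrt(w))
  unscaled <- chol2inv(chol(XtWX))
  df_resid <- n - p
  phi <- sum((y - mu)^2 / mu) / df_resid
  vcov <- phi * unscaled
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(list(
    beta = setNames(beta, colnames(X)), vcov = vcov, dispersion = phi,
    deviance = dev_of(mu), n_obs = n, df_resid = df_resid,
    converged = converged, iter = iter, fitted = mu, design = dsn
  ), class = "qp_fit")
}

#' Linear combination of coefficients with its standard error
#'
#' For a contrast vector `c`, returns `c'beta` and `sqrt(c' vcov c)`; the
#' building block for cumulative relative risks and their intervals.
#'
#' @param fit a `qp_fit`.
#' @param contrast numeric vector, same length as the coefficient vector.
#' @return one-row tibble: `estimate`, `se`.
#' @export
linear_combination <- function(fit, contrast) {
  stopifnot(inherits(fit, "qp_fit"))
  if (length(contrast) != length(fit$beta)) {
    abort(sprintf("contrast has length %d; expected %d",
                  length(contrast), length(fit$beta)))
  }
  est <- sum(contrast * fit$beta)
  se <- sqrt(drop(t(contrast) %*% fit$vcov %*% contrast))
  tibble::tibble(estimate = est, se = se)
}

#' @export
print.qp_fit <- function(x, ...) {
  cat(sprintf(
    "<qp_fit> %d obs, %d coef, dispersion %.3f, deviance %.1f (%sconverged, %d iter)\n",
    x$n_obs, length(x$beta), x$dispersion, x$deviance,
    if (x$converged) "" else "NOT ", x$iter
  ))
  invisible(x)
}

#' Tidy a quasi-Poisson fit
#'
#' @param x a `qp_fit`.
#' @param ... unused.
#' @return tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value` (Wald, normal reference).
#' @export
tidy.qp_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  stat <- x$beta / se
  tibble::tibble(
    term = names(x$beta), estimate = unname(x$beta), std.error = unname(se),
    statistic = unname(stat), p.value = unname(2 * pnorm(-abs(stat)))
  )
}

#' @rdname tidy.qp_fit
#' @export
glance.qp_fit <- function(x, ...) {
  tibble::tibble(
    dispersion = x$dispersion, deviance = x$deviance, nobs = x$n_obs,
    df.residual = x$df_resid, converged = x$converged, iter = x$iter
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
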