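#' @importFrom rlang abort warn .data %||%
#' @importFrom stats median quantile rnorm rpois rnbinom runif approx lm
#'   predict coef qnorm pnorm setNames optim sd var
#' @importFrom utils read.csv write.csv head tail
NULL

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Winter-season helpers
#'
#' Winter is defined as 1 November to 31 March inclusive. Each winter season
#' is treated as an independent series and is labelled by the calendar year
#' of its January: the 2008/09 winter has label 2009.
#'
#' @param date a `Date` vector.
#' @return `is_winter()` returns a logical vector; `winter_label()` returns an
#'   integer year label (`NA` outside winter).
#' @examples
#' is_winter(as.Date("2009-01-15"))
#' winter_label(as.Date(c("2008-11-01", "2009-03-31", "2009-06-01")))
#' @export
is_winter <- function(date) {
  m <- as.integer(format(date, "%m"))
  m >= 11L | m <= 3L
}

#' @rdname is_winter
#' @export
winter_label <- function(date) {
  m <- as.integer(format(date, "%m"))
  y <- as.integer(format(date, "%Y"))
  out <- ifelse(m >= 11L, y + 1L, ifelse(m <= 3L, y, NA_integer_))
  as.integer(out)
}

day_of_year <- function(date) as.integer(format(date, "%j"))

# Longest run of TRUE in a logical vector (0 when none).
longest_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}
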