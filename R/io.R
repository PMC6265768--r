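#' Packaged replica of the national and area estimate table
#'
#' Loads the packaged table of winter temperature summaries (lowest, first
#' percentile, median, highest), cumulative relative risks with 95%
#' intervals, attributable fractions, and 2015 fuel-poverty percentages for
#' the 44 English STP areas plus the England row. Log relative risks and
#' their standard errors (recovered from the intervals via [se_from_ci()])
#' are derived on load. The fixture is validated against anchor values; any
#' mismatch means the packaged file was altered and is an error.
#'
#' @return tibble with 45 rows: `area`, `stp`, `lowest`, `p1`, `median`,
#'   `highest`, `rr`, `lo`, `hi`, `paf`, `fuel_poverty`, `is_national`,
#'   `log_rr`, `se`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "stp_table1.csv", package = "coldsnap",
                      mustWork = TRUE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  tbl <- tibble::as_tibble(raw) |>
    dplyr::mutate(
      stp = suppressWarnings(as.integer(.data$stp)),
      is_national = .data$area == "England",
      log_rr = log(.data$rr),
      se = se_from_ci(.data$lo, .data$hi)
    )
  ok <- nrow(tbl) == 45L &&
    sum(tbl$is_national) == 1L &&
    isTRUE(all.equal(tbl$fuel_poverty[tbl$is_national], 11.04)) &&
    isTRUE(all.equal(tbl$rr[tbl$area == "Somerset"], 1.74)) &&
    isTRUE(all.equal(sum(tbl$rr), 62.41, tolerance = 1e-8))
  if (!ok) abort("packaged estimate table failed its consistency check")
  tbl
}

#' Read a daily death-count series
#'
#' Reads a delimited file with columns `area_id`, `date` (ISO-8601),
#' `deaths`, and optionally `stratum`. Validation is strict: dates must
#' parse, counts must be nonnegative integers, no `(area, date, stratum)`
#' may repeat, and within each area's observed range every winter day
#' (November--March) must be present -- a missing winter day is rejected
#' rather than silently treated as zero deaths.
#'
#' @param path file path; lines starting `#` are treated as metadata and
#'   skipped.
#' @return tibble sorted by area and date.
#' @export
read_health_series <- function(path) {
  raw <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("area_id", "date", "deaths")
  if (!all(need %in% names(raw))) {
    abort(sprintf("file must have columns %s", paste(need, collapse = ", ")))
  }
  d <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(d)) {
    bad <- which(is.na(d))
    abort(sprintf("non-ISO date at row(s) %s (e.g. '%s')",
                  paste(head(bad, 5), collapse = ", "), raw$date[bad[1]]))
  }
  if (any(raw$deaths < 0) || any(raw$deaths != floor(raw$deaths))) {
    bad <- which(raw$deaths < 0 | raw$deaths != floor(raw$deaths))
    abort(sprintf("deaths must be nonnegative integers; offending row(s) %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  tbl <- tibble::as_tibble(raw) |> dplyr::mutate(date = d)
  key_cols <- intersect(c("area_id", "date", "stratum"), names(tbl))
  dup <- duplicated(tbl[key_cols])
  if (any(dup)) {
    abort(sprintf("duplicate (%s) at row(s) %s",
                  paste(key_cols, collapse = ", "),
                  paste(head(which(dup), 5), collapse = ", ")))
  }
  check_winter_gaps <- function(df, id) {
    all_days <- seq(min(df$date), max(df$date), by = "day")
    missing <- setdiff(all_days[is_winter(all_days)], df$date)
    if (length(missing) > 0) {
      abort(sprintf("area %s is missing %d winter day(s), first %s", id,
                    length(missing), as.Date(missing[1], origin = "1970-01-01")))
    }
  }
  tbl |>
    dplyr::group_by(.data$area_id) |>
    dplyr::group_walk(~ check_winter_gaps(.x, .y$area_id))
  dplyr::arrange(tbl, .data$area_id, .data$date)
}

#' Read station temperature series
#'
#' Delimited file with `station_id`, `date` (ISO-8601), `temp`, optionally
#' `area_id`; missing station-days may be absent rows or `NA` temperatures.
#'
#' @inheritParams read_health_series
#' @return tibble sorted by station and date.
#' @export
read_station_series <- function(path) {
  raw <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("station_id", "date", "temp")
  if (!all(need %in% names(raw))) {
    abort(sprintf("file must have columns %s", paste(need, collapse = ", ")))
  }
  d <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(d)) abort("station file contains non-ISO dates")
  tibble::as_tibble(raw) |>
    dplyr::mutate(date = d) |>
    dplyr::arrange(.data$station_id, .data$date)
}

#' Write a result table with a metadata header
#'
#' Every pipeline output carries a `#`-prefixed header recording the
#' package version, timestamp-free settings and seed, so results are
#' auditable; [read_health_series()] and friends skip these lines.
#'
#' @param data data frame to write.
#' @param path destination CSV path.
#' @param meta character vector of `key: value` lines (written as
#'   `# key: value`).
#' @return `path`, invisibly.
#' @export
write_output_table <- function(data, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# coldsnap %s",
                     as.character(utils::packageVersion("coldsnap"))), con)
  for (m in meta) writeLines(paste0("# ", m), con)
  write.csv(data, con, row.names = FALSE)
  invisible(path)
}
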