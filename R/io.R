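#' Read raw replicate search-volume observations from CSV
#'
#' Expected columns: `country,language,term,week_start,value,replicate_id`
#' with integer values in 0--100 and `week_start` an ISO-8601 Monday.
#'
#' @param path CSV file path.
#' @return Validated tibble of raw observations.
#' @export
read_trends_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         country = readr::col_character(),
                         language = readr::col_character(),
                         term = readr::col_character(),
                         week_start = readr::col_date(),
                         value = readr::col_double(),
                         replicate_id = readr::col_character()))
  validate_raw_trends(x)
  x
}

#' @rdname read_trends_csv
#' @param x Table to write.
#' @export
write_trends_csv <- function(x, path) {
  validate_raw_trends(x)
  readr::write_csv(x, path)
  invisible(path)
}

#' Read a countermeasure calendar from an ECDC-style CSV
#'
#' Expected columns: `country,measure,date_start,date_end`, where the printed
#' end date is inclusive (as in ECDC response-measure exports). On ingest all
#' intervals become half-open `[date_start, date_end + 1 day)` and, per
#' `(country, measure)`, overlapping or touching intervals are merged and
#' sorted.
#'
#' @param path CSV file path. An empty file yields a valid calendar with no
#'   measures.
#' @return Tibble with columns `country`, `measure`, `start`, `end` (the
#'   interval `[start, end)` in days).
#' @export
read_measure_calendar <- function(path) {
  empty_cal <- tibble::tibble(country = character(), measure = character(),
                              start = as.Date(character()),
                              end = as.Date(character()))
  if (file.size(path) == 0) return(empty_cal)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  if (nrow(x) == 0) return(empty_cal)
  need <- c("country", "measure", "date_start", "date_end")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("measure calendar lacks columns: ",
                         paste(miss, collapse = ", "))
  ds <- as.Date(x$date_start); de <- as.Date(x$date_end)
  bad <- which(is.na(ds) | is.na(de) | is.na(x$country) | is.na(x$measure))
  if (length(bad)) stop("row ", bad[1], ": malformed measure calendar row")
  bad <- which(de < ds)
  if (length(bad)) stop("row ", bad[1], ": end date before start date")
  x <- tibble::tibble(country = x$country, measure = x$measure,
                      start = ds, end = de + 1L)
  x <- dplyr::group_by(x, .data$country, .data$measure)
  x <- dplyr::reframe(x, merge_intervals(.data$start, .data$end))
  dplyr::arrange(x, .data$country, .data$measure, .data$start)
}

#' Read per-country population sizes
#'
#' @param path CSV with columns `country,population` (persons, positive).
#' @return Named numeric vector of populations keyed by country code.
#' @export
read_population_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("country", "population") %in% names(x)))
    stop("population table needs columns country, population")
  if (any(!is.finite(x$population) | x$population <= 0))
    stop("populations must be positive")
  stats::setNames(as.numeric(x$population), x$country)
}

#' Read daily reported case counts
#'
#' @param path CSV with columns `country,date,cases`.
#' @return Tibble with `country`, `date` (`Date`), `cases` (non-negative).
#' @export
read_cases_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         country = readr::col_character(),
                         date = readr::col_date(),
                         cases = readr::col_double()))
  if (any(!is.finite(x$cases) | x$cases < 0)) stop("case counts must be >= 0")
  x
}

#' Read native-speaker language shares from a YAML config
#'
#' The config maps country codes to `language: share` entries, shares being
#' raw percentages as published (they need not sum to 100; residuals are
#' non-native speakers).
#'
#' @param path YAML file path.
#' @return Named list: country -> named numeric vector of shares.
#' @export
read_language_shares <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(e) unlist(e))
}

#' Write/read a result table (CSV round-trip)
#'
#' Plain-CSV persistence for aggregate tables and triplet dumps;
#' `read_table_csv(write_table(x, p))` reproduces `x`.
#'
#' @param x Data frame to write.
#' @param path CSV file path.
#' @export
write_table <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
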