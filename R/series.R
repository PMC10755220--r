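#' Weekly relative-search-volume series
#'
#' A `trend_series` holds one weekly relative-search-volume (RSV) series with
#' its provenance: country, language, term (or term group), and the half-open
#' period it covers. Raw Google-Trends-style observations are integers in
#' 0--100; consolidated series are unrounded reals in \eqn{[0, 100]} with an
#' optional per-week standard deviation.
#'
#' @param country ISO-3166 country code (or `"EU"` for the combined series).
#' @param term Search-term (variant or group) identifier.
#' @param week_start `Date` vector of week Mondays, regular 7-day spacing.
#' @param value Non-negative weekly values.
#' @param language ISO-639 language code, or `NA` for merged series.
#' @param sd Optional per-week standard deviation (same length as `value`).
#' @param n_replicates Number of replicate observations consolidated into
#'   this series.
#' @param empty Logical; `TRUE` marks the all-zero ("empty") series Google
#'   Trends returns for queries below its volume threshold. Defaults to
#'   `all(value == 0)`.
#' @return An object of class `trend_series`.
#' @export
trend_series <- function(country, term, week_start, value,
                         language = NA_character_, sd = NULL,
                         n_replicates = 1L, empty = NULL) {
  week_start <- as.Date(week_start)
  if (length(week_start) != length(value))
    stop("week_start and value must have equal length")
  if (length(value) < 1L) stop("a trend series needs at least one week")
  if (!all(is_monday(week_start)))
    stop("week_start entries must be Mondays")
  if (length(week_start) > 1L &&
      any(diff(as.numeric(week_start)) != 7))
    stop("week_start must advance in regular 7-day steps")
  if (any(!is.finite(value)) || any(value < 0))
    stop("values must be finite and non-negative")
  if (!is.null(sd)) {
    if (length(sd) != length(value)) stop("sd must match value length")
    if (any(!is.finite(sd)) || any(sd < 0)) stop("sd must be finite and >= 0")
  }
  structure(
    list(country = country, language = language, term = term,
         week_start = week_start, value = as.numeric(value), sd = sd,
         n_replicates = as.integer(n_replicates),
         empty = empty %||% all(value == 0)),
    class = "trend_series")
}

#' @export
print.trend_series <- function(x, ...) {
  cat(sprintf("<trend_series> %s/%s '%s': %d weeks [%s, %s], %s%s\n",
              x$country, x$language %||% NA, x$term, length(x$value),
              format(min(x$week_start)), format(max(x$week_start) + 7L),
              if (x$empty) "empty" else sprintf("max %.6g", max(x$value)),
              if (is.null(x$sd)) "" else ", with sd"))
  invisible(x)
}

#' @export
length.trend_series <- function(x) length(x$value)

#' @rdname trend_series
#' @param x Object to test or convert.
#' @export
is_trend_series <- function(x) inherits(x, "trend_series")

#' @rdname trend_series
#' @export
as_tibble_series <- function(x) {
  tibble::tibble(country = x$country, language = x$language, term = x$term,
                 week_start = x$week_start, value = x$value,
                 sd = if (is.null(x$sd)) NA_real_ else x$sd)
}

# Assert that a list of series shares one week axis; returns the axis.
shared_week_axis <- function(series_list) {
  ax <- series_list[[1]]$week_start
  for (s in series_list[-1]) {
    if (length(s$week_start) != length(ax) || any(s$week_start != ax))
      stop("series do not share a common week axis")
  }
  ax
}

# Restrict a series to the weeks whose Monday falls inside [start, end).
series_window <- function(x, start, end) {
  keep <- x$week_start >= as.Date(start) & x$week_start < as.Date(end)
  if (!any(keep)) stop("interval contains no weeks of the series")
  trend_series(x$country, x$term, x$week_start[keep], x$value[keep],
               language = x$language, sd = x$sd[keep],
               n_replicates = x$n_replicates)
}

#' Validate a long table of raw replicate observations
#'
#' Raw observations are Google-Trends-style exports: integer values 0--100,
#' weeks keyed by their Monday. Partially covered weeks are rejected rather
#' than silently truncated.
#'
#' @param x Tibble with columns `country`, `language`, `term`, `week_start`,
#'   `value`, `replicate_id`.
#' @return `x`, invisibly, after validation.
#' @export
validate_raw_trends <- function(x) {
  need <- c("country", "language", "term", "week_start", "value", "replicate_id")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("raw trends table lacks columns: ",
                         paste(miss, collapse = ", "))
  x$week_start <- as.Date(x$week_start)
  bad <- which(is.na(x$week_start))
  if (length(bad)) stop("row ", bad[1], ": unparseable week_start")
  bad <- which(!is_monday(x$week_start))
  if (length(bad)) stop("row ", bad[1],
                        ": week_start is not a Monday (partial weeks are rejected)")
  bad <- which(!is.finite(x$value) | x$value < 0 | x$value > 100)
  if (length(bad)) stop("row ", bad[1], ": value outside [0, 100]")
  bad <- which(x$value != round(x$value))
  if (length(bad)) stop("row ", bad[1],
                        ": raw relative search volume must be integer-valued")
  invisible(x)
}

#' Rebuild `trend_series` objects from a long consolidated table
#'
#' Inverse of [as_tibble_series()] over a table holding several series
#' (columns `country`, `language`, `term`, `week_start`, `value`,
#' optionally `sd`).
#'
#' @param tbl Long tibble of consolidated series.
#' @return Named list of `trend_series`, keyed `country|term`.
#' @export
series_from_table <- function(tbl) {
  tbl$week_start <- as.Date(tbl$week_start)
  if (!"language" %in% names(tbl)) tbl$language <- NA_character_
  key <- paste(tbl$country, tbl$term, sep = "|")
  out <- lapply(split(seq_len(nrow(tbl)), key), function(idx) {
    d <- tbl[idx, , drop = FALSE]
    d <- d[order(d$week_start), , drop = FALSE]
    sdv <- if ("sd" %in% names(d) && !anyNA(d$sd)) d$sd else NULL
    trend_series(d$country[1], d$term[1], d$week_start, d$value,
                 language = d$language[1], sd = sdv)
  })
  out
}

#' Split a raw trends table into replicate sets
#'
#' Groups a validated raw-observation table into replicate sets: one entry
#' per (country, language, term), each a list of `trend_series` replicates
#' sharing the same week axis.
#'
#' @param raw Raw-observation tibble (see [validate_raw_trends()]).
#' @return Named list keyed `country|language|term`.
#' @export
raw_to_replicate_sets <- function(raw) {
  validate_raw_trends(raw)
  raw <- dplyr::arrange(raw, .data$country, .data$language, .data$term,
                        .data$replicate_id, .data$week_start)
  keys <- unique(raw[, c("country", "language", "term")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sub <- dplyr::filter(raw, .data$country == k$country,
                         .data$language == k$language, .data$term == k$term)
    reps <- lapply(split(sub, sub$replicate_id), function(d)
      trend_series(k$country, k$term, d$week_start, d$value,
                   language = k$language))
    shared_week_axis(reps)
    out[[paste(k$country, k$language, k$term, sep = "|")]] <- reps
  }
  out
}
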