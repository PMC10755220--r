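#' @importFrom rlang %||% .data
#' @importFrom stats median pnorm rbinom sd var
#' @importFrom utils head tail
NULL

# Round half away from zero, the convention used for reported percentages.
# base::round() rounds half to even, which does not reproduce printed tables.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic 31-bit seed derived from a master seed and an identity string,
# so that per-(country, term, replicate) RNG streams are keyed by identity:
# adding a country or replicate never perturbs the draws of the others.
derive_seed <- function(master, key) {
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 31 + cc) %% 2147483647
  as.integer((h + (as.numeric(master) %% 2147483647) * 7919) %% 2147483647)
}

is_monday <- function(d) as.integer(format(d, "%u")) == 1L

#' Weekly axis of a half-open date interval
#'
#' Weeks are keyed by their Monday. The interval start must itself be a
#' Monday and the interval must span a whole number of weeks.
#'
#' @param start,end `Date` scalars; the interval is `[start, end)`.
#' @return `Date` vector of week Mondays.
#' @export
period_weeks <- function(start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (!is_monday(start)) stop("period start must be a Monday (ISO week key)")
  if (end <= start) stop("period end must be after start")
  if (as.numeric(end - start) %% 7 != 0)
    stop("period must span a whole number of weeks")
  seq(start, end - 1L, by = "7 days")
}

# Merge sorted half-open intervals; touching or overlapping runs coalesce.
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L)
    return(tibble::tibble(start = as.Date(character()), end = as.Date(character())))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- as.Date(character()); out_e <- as.Date(character())
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  tibble::tibble(start = c(out_s, ms), end = c(out_e, me))
}

# Number of days of week [week_start, week_start + 7) covered by the
# half-open intervals (vectorised over weeks).
week_coverage_days <- function(week_start, start, end) {
  vapply(week_start, function(ws) {
    we <- ws + 7L
    sum(pmax(0, as.numeric(pmin(end, we) - pmax(start, ws))))
  }, numeric(1))
}
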