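#' Mann-Whitney U test with exact small-sample enumeration
#'
#' Two-sided Mann-Whitney U comparison of two independent samples of weekly
#' search-volume values. For small problems (`n1 * n2 <= exact_cap`) the
#' permutation distribution of the midrank sum is computed exactly by
#' dynamic programming — valid under ties, and identical to brute-force
#' enumeration of all group assignments. Larger problems use the normal
#' approximation with tie correction and a 0.5 continuity correction.
#' Direction of the effect is the sign of `median(x) - median(y)`.
#'
#' @param x Values of the first group (e.g. weeks during a countermeasure).
#' @param y Values of the second group (weeks outside it).
#' @param exact_cap Use exact enumeration when `n1 * n2` does not exceed
#'   this (default 400).
#' @return List with `U` (U statistic of `x`), `p` (two-sided), `method`
#'   (`"exact"` or `"normal-approx"`), `direction`
#'   (`"increase"`, `"decrease"`, `"none"`), and sample sizes `n1`, `n2`.
#' @export
mann_whitney <- function(x, y, exact_cap = 400) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups need at least one value")
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mx <- median(x); my <- median(y)
  direction <- if (mx > my) "increase" else if (mx < my) "decrease" else "none"
  if (length(unique(c(x, y))) == 1L) {
    return(list(U = u1, p = 1, method = "degenerate", direction = "none",
                n1 = n1, n2 = n2))
  }
  if (n1 * n2 <= exact_cap) {
    p <- exact_rank_p(r, n1)
    method <- "exact"
  } else {
    n <- n1 + n2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = u1, p = 1, method = "normal-approx",
                                 direction = "none", n1 = n1, n2 = n2))
    z <- u1 - n1 * n2 / 2
    z <- z - sign(z) * 0.5            # continuity correction
    p <- min(1, 2 * pnorm(-abs(z) / sqrt(sigma2)))
    method <- "normal-approx"
  }
  list(U = u1, p = p, method = method, direction = direction,
       n1 = n1, n2 = n2)
}

# Exact two-sided p for the rank-sum permutation distribution, ties allowed.
# r: midranks of the pooled sample; first n1 entries belong to group x.
# Counts subsets of size k (k = smaller group, by symmetry) whose doubled
# rank sum deviates from its mean by at least the observed deviation, via a
# subset-sum dynamic programme over the doubled (integer) midranks.
exact_rank_p <- function(r, n1) {
  n <- length(r)
  n2 <- n - n1
  r2 <- as.integer(round(2 * r))       # midranks doubled -> integers
  if (n1 <= n2) {
    k <- n1
    s_obs <- sum(r2[seq_len(n1)])
  } else {
    k <- n2
    s_obs <- sum(r2[-seq_len(n1)])
  }
  mu <- k * (n + 1)                     # E[doubled rank sum of k draws]
  dev <- abs(s_obs - mu)
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(k)])
  # ways[i, s+1] = number of size-(i-1) subsets with doubled rank sum s
  ways <- matrix(0, nrow = k + 1, ncol = smax + 1)
  ways[1, 1] <- 1
  for (v in r2) {
    imax <- k
    for (i in seq(imax, 1)) {
      src <- seq_len(smax + 1 - v)
      ways[i + 1, src + v] <- ways[i + 1, src + v] + ways[i, src]
    }
  }
  counts <- ways[k + 1, ]
  s_vals <- seq(0, smax)
  extreme <- abs(s_vals - mu) >= dev
  sum(counts[extreme]) / choose(n, k)
}

#' Classify a p-value into significance tiers
#'
#' Screening uses two tiers: `p <= 0.05` is significant and `p < 0.01`
#' very significant. A missing p-value (empty series, measure never active,
#' or an empty comparison group) is `invalid`.
#'
#' @param p A p-value in `[0, 1]`, or `NA`/`NULL` when the test could not
#'   be performed.
#' @return One of `"invalid"`, `"very_significant"`, `"significant"`,
#'   `"not_significant"`.
#' @export
classify <- function(p) {
  if (is.null(p) || length(p) == 0 || is.na(p)) return("invalid")
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (p < 0.01) "very_significant"
  else if (p <= 0.05) "significant"
  else "not_significant"
}

invalid_split <- function(reason) {
  structure(list(valid = FALSE, reason = reason), class = "group_split")
}

#' Split a series into weeks during vs. outside a countermeasure
#'
#' A week counts as "during" when at least `coverage` of its seven days fall
#' inside an active interval of the measure (default 4/7, a majority of
#' days). All remaining weeks form the comparison group; with
#' `before_only = TRUE` the comparison group is restricted to weeks before
#' the measure's first activation. The split is `invalid` (not an error)
#' when the measure never applies in this country, when either group is
#' empty, or when the series itself is empty.
#'
#' @param series Consolidated `trend_series`.
#' @param calendar Measure calendar tibble (`country`, `measure`, `start`,
#'   `end`) as from [read_measure_calendar()].
#' @param measure Measure name.
#' @param coverage Fraction of a week's days required for "during"
#'   membership (default `4/7`).
#' @param before_only Restrict the comparison group to pre-first-activation
#'   weeks.
#' @return A `group_split`: either invalid with a `reason`, or valid with
#'   `during`, `outside` value vectors and a `rule` description.
#' @export
split_by_measure <- function(series, calendar, measure, coverage = 4 / 7,
                             before_only = FALSE) {
  if (series$empty) return(invalid_split("empty series"))
  cal <- calendar[calendar$country == series$country &
                    calendar$measure == measure, , drop = FALSE]
  if (nrow(cal) == 0) return(invalid_split("measure not implemented"))
  days <- week_coverage_days(series$week_start, cal$start, cal$end)
  during <- days >= coverage * 7 - 1e-9
  outside <- !during
  if (before_only) outside <- outside & series$week_start < min(cal$start)
  if (!any(during)) return(invalid_split("measure never active in period"))
  if (!any(outside)) return(invalid_split("no comparison weeks"))
  structure(list(valid = TRUE,
                 during = series$value[during],
                 outside = series$value[outside],
                 n_during = sum(during), n_outside = sum(outside),
                 rule = sprintf("week during iff >= %.3f of days active%s",
                                coverage,
                                if (before_only) "; outside = pre-first-activation only" else "")),
            class = "group_split")
}

#' Split a series at the first confirmed case
#'
#' Weeks strictly before the week containing the first confirmed case form
#' the pre-pandemic group ("outside"); that week and all later weeks form
#' the pandemic group ("during").
#'
#' @param series Consolidated `trend_series`.
#' @param first_case_date `Date` of the first confirmed case.
#' @return A `group_split` (invalid when the date falls outside the series
#'   period or the series is empty).
#' @export
split_by_first_case <- function(series, first_case_date) {
  if (series$empty) return(invalid_split("empty series"))
  d <- as.Date(first_case_date)
  if (length(d) != 1 || is.na(d)) return(invalid_split("no first-case date"))
  if (d < min(series$week_start) || d >= max(series$week_start) + 7L)
    return(invalid_split("first-case date outside series period"))
  during <- series$week_start + 7L > d       # week containing d, and later
  structure(list(valid = TRUE,
                 during = series$value[during],
                 outside = series$value[!during],
                 n_during = sum(during), n_outside = sum(!during),
                 rule = "during = first-case week and later"),
            class = "group_split")
}

#' Test one (country, term, countermeasure) triplet
#'
#' Applies [split_by_measure()] then [mann_whitney()] and [classify()],
#' returning one result row. An invalid split yields status `invalid` with
#' no p-value, mirroring how an empty Google Trends series or an
#' unimplemented measure is handled.
#'
#' @param series Consolidated `trend_series` for one (country, term).
#' @param calendar Measure calendar tibble.
#' @param measure Measure name.
#' @param split A precomputed `group_split` (overrides `calendar`/`measure`).
#' @inheritParams split_by_measure
#' @inheritParams mann_whitney
#' @return One-row tibble: `country`, `term`, `measure`, `status`,
#'   `p_value`, `direction`, `n_during`, `n_outside`.
#' @export
test_triplet <- function(series, calendar = NULL, measure = NA_character_,
                         split = NULL, coverage = 4 / 7, before_only = FALSE,
                         exact_cap = 400) {
  sp <- split %||% split_by_measure(series, calendar, measure,
                                    coverage = coverage,
                                    before_only = before_only)
  if (!sp$valid) {
    return(tibble::tibble(country = series$country, term = series$term,
                          measure = measure, status = "invalid",
                          p_value = NA_real_, direction = "none",
                          n_during = NA_integer_, n_outside = NA_integer_))
  }
  mw <- mann_whitney(sp$during, sp$outside, exact_cap = exact_cap)
  tibble::tibble(country = series$country, term = series$term,
                 measure = measure, status = classify(mw$p),
                 p_value = mw$p, direction = mw$direction,
                 n_during = sp$n_during, n_outside = sp$n_outside)
}

#' Screen every (country, term, measure) triplet
#'
#' @param series_list List of consolidated country-level `trend_series`
#'   (one per country and term group).
#' @param calendar Measure calendar tibble covering all countries.
#' @param measures Measure names to screen (default: all in the calendar).
#' @inheritParams test_triplet
#' @return Tibble of triplet results, one row per combination.
#' @export
run_triplet_tests <- function(series_list, calendar,
                              measures = unique(calendar$measure),
                              coverage = 4 / 7, before_only = FALSE,
                              exact_cap = 400) {
  rows <- list()
  for (s in series_list) {
    for (m in measures) {
      rows[[length(rows) + 1L]] <-
        test_triplet(s, calendar, m, coverage = coverage,
                     before_only = before_only, exact_cap = exact_cap)
    }
  }
  dplyr::bind_rows(rows)
}
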