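sig_statuses <- c("significant", "very_significant")

#' Percentage of countries with a (very) significant change
#'
#' For one (measure, term), the fraction of countries whose screening test
#' is significant or very significant, among countries with a valid test —
#' invalid countries (measure never implemented, empty series) are excluded
#' from the denominator. For example, 17 significant of 27 valid countries
#' gives 63%.
#'
#' @param results Triplet-result tibble for a single (measure, term), one
#'   row per country (columns `country`, `status`).
#' @return List: `pct` (integer-rounded), `pct_raw` (3-decimal internal),
#'   `n_valid`, `n_sig`, `valid` (`FALSE` when every country is invalid).
#' @export
country_fraction <- function(results) {
  valid <- results$status != "invalid"
  n_valid <- sum(valid)
  if (n_valid == 0)
    return(list(pct = NA_real_, pct_raw = NA_real_, n_valid = 0L,
                n_sig = 0L, valid = FALSE))
  n_sig <- sum(results$status[valid] %in% sig_statuses)
  raw <- round_half_up(100 * n_sig / n_valid, 3)
  list(pct = round_half_up(raw, 0), pct_raw = raw,
       n_valid = as.integer(n_valid), n_sig = as.integer(n_sig),
       valid = TRUE)
}

#' Population-weighted percentage of countries with significant change
#'
#' As [country_fraction()], but each country contributes its population
#' size instead of one vote: the share of the (valid-country) population
#' living where the measure shows a (very) significant change. Reported to
#' one decimal.
#'
#' @param results Triplet-result tibble for a single (measure, term).
#' @param populations Named numeric vector covering every valid country.
#' @return List: `pct` (1-decimal), `pct_raw`, `n_valid`, `n_sig`, `valid`.
#' @export
weighted_country_fraction <- function(results, populations) {
  valid <- results$status != "invalid"
  if (!any(valid))
    return(list(pct = NA_real_, pct_raw = NA_real_, n_valid = 0L,
                n_sig = 0L, valid = FALSE))
  ctys <- results$country[valid]
  miss <- setdiff(ctys, names(populations))
  if (length(miss)) stop("missing population for: ",
                         paste(miss, collapse = ", "))
  sig <- results$status[valid] %in% sig_statuses
  raw <- 100 * sum(populations[ctys[sig]]) / sum(populations[ctys])
  list(pct = round_half_up(raw, 1), pct_raw = raw,
       n_valid = as.integer(sum(valid)), n_sig = as.integer(sum(sig)),
       valid = TRUE)
}

#' Term-independent roll-up for one measure
#'
#' Eliminates the search-term dimension in one of two senses: `"any-term"`
#' counts a country as significant when any of its terms shows a (very)
#' significant change (denominator: countries with at least one valid
#' term); `"all-pairs"` computes the fraction over all valid
#' (country x term) pairs.
#'
#' @param results Triplet-result tibble for one measure, rows over
#'   countries and terms.
#' @param mode `"any-term"` or `"all-pairs"`.
#' @param populations Optional named populations; when supplied the
#'   population-weighted variant is also returned (for `"all-pairs"` each
#'   pair carries its country's population).
#' @return List: `pct`, `pct_raw`, `n_valid`, `n_sig`, and `pct_weighted`
#'   when populations are given.
#' @export
any_term_fraction <- function(results, mode = c("any-term", "all-pairs"),
                              populations = NULL) {
  mode <- match.arg(mode)
  if (mode == "any-term") {
    per_cty <- dplyr::summarise(
      dplyr::group_by(results, .data$country),
      status = if (all(.data$status == "invalid")) "invalid"
               else if (any(.data$status %in% sig_statuses)) "significant"
               else "not_significant",
      .groups = "drop")
    base <- country_fraction(per_cty)
    base$pct <- round_half_up(base$pct_raw %||% NA_real_, 1)
    if (!is.null(populations))
      base$pct_weighted <- weighted_country_fraction(per_cty, populations)$pct
    return(base)
  }
  valid <- results$status != "invalid"
  n_valid <- sum(valid)
  if (n_valid == 0)
    return(list(pct = NA_real_, pct_raw = NA_real_, n_valid = 0L,
                n_sig = 0L, valid = FALSE))
  sig <- results$status %in% sig_statuses
  raw <- 100 * sum(sig) / n_valid
  out <- list(pct = round_half_up(raw, 1), pct_raw = raw,
              n_valid = as.integer(n_valid), n_sig = as.integer(sum(sig)),
              valid = TRUE)
  if (!is.null(populations)) {
    pv <- populations[results$country[valid]]
    ps <- populations[results$country[valid & sig]]
    out$pct_weighted <- round_half_up(100 * sum(ps) / sum(pv), 1)
  }
  out
}

#' Rank terms by their per-country significance percentage
#'
#' For one measure, terms are ordered by the percentage of countries with a
#' (very) significant change; the first-ranked term is the measure's
#' "dominating effect". Ties break by the population-weighted percentage,
#' then alphabetically, and are flagged.
#'
#' @param term_pcts Tibble with columns `term`, `pct` and optionally
#'   `pct_weighted`.
#' @return Tibble ordered by rank with columns `term`, `pct`,
#'   `pct_weighted`, `rank`, `tie`.
#' @export
dominating_effect <- function(term_pcts) {
  x <- tibble::as_tibble(term_pcts)
  if (!"pct_weighted" %in% names(x)) x$pct_weighted <- NA_real_
  x <- x[!is.na(x$pct), , drop = FALSE]
  if (nrow(x) == 0) stop("no valid term percentages to rank")
  o <- order(-x$pct, -ifelse(is.na(x$pct_weighted), -Inf, x$pct_weighted),
             x$term)
  x <- x[o, , drop = FALSE]
  x$rank <- seq_len(nrow(x))
  x$tie <- duplicated(x$pct) | duplicated(x$pct, fromLast = TRUE)
  x
}

#' Aggregate triplet results into per-measure tables
#'
#' Builds the two headline tables of the screening: per (measure, term) the
#' unweighted percentage of countries with a (very) significant change
#' (integer-rounded) and the population-weighted percentage (one decimal),
#' the any-term and all-pairs roll-ups per measure, and for each measure the
#' first and second dominating term.
#'
#' @param triplets Triplet-result tibble from [run_triplet_tests()].
#' @param populations Named numeric population vector.
#' @return List of tibbles: `by_term` (one row per measure x term, plus
#'   `ANY` / `ALL-PAIRS` roll-up rows) and `dominating` (top two terms per
#'   measure).
#' @export
aggregate_tables <- function(triplets, populations) {
  rows <- list(); doms <- list()
  for (m in unique(triplets$measure)) {
    tm <- triplets[triplets$measure == m, , drop = FALSE]
    term_rows <- list()
    for (tr in unique(tm$term)) {
      tt <- tm[tm$term == tr, , drop = FALSE]
      cf <- country_fraction(tt)
      wf <- if (cf$valid) weighted_country_fraction(tt, populations)
            else list(pct = NA_real_)
      term_rows[[tr]] <- tibble::tibble(
        measure = m, term = tr, pct_unweighted = cf$pct,
        pct_weighted = wf$pct, n_valid = cf$n_valid, n_sig = cf$n_sig)
    }
    tr_tbl <- dplyr::bind_rows(term_rows)
    any_t <- any_term_fraction(tm, "any-term", populations)
    all_p <- any_term_fraction(tm, "all-pairs", populations)
    rows[[m]] <- dplyr::bind_rows(
      tr_tbl,
      tibble::tibble(measure = m, term = "ANY",
                     pct_unweighted = any_t$pct,
                     pct_weighted = any_t$pct_weighted %||% NA_real_,
                     n_valid = any_t$n_valid, n_sig = any_t$n_sig),
      tibble::tibble(measure = m, term = "ALL-PAIRS",
                     pct_unweighted = all_p$pct,
                     pct_weighted = all_p$pct_weighted %||% NA_real_,
                     n_valid = all_p$n_valid, n_sig = all_p$n_sig))
    rankable <- tr_tbl[!is.na(tr_tbl$pct_unweighted), , drop = FALSE]
    if (nrow(rankable)) {
      dom <- dominating_effect(tibble::tibble(
        term = rankable$term, pct = rankable$pct_unweighted,
        pct_weighted = rankable$pct_weighted))
      doms[[m]] <- tibble::tibble(measure = m,
                                  dplyr::slice_head(dom, n = 2))
    }
  }
  list(by_term = dplyr::bind_rows(rows), dominating = dplyr::bind_rows(doms))
}

#' Pre/post first-case shift classification per term
#'
#' For each term, both pan-European datasets (unweighted and
#' population-weighted) are split at the first confirmed case
#' ([split_by_first_case()]) and screened; the result is one of
#' `increase` / `decrease` / `none` per dataset with its significance tier.
#' Terms whose two datasets disagree are flagged `discordant` (e.g. a
#' decrease in one dataset and no change in the other).
#'
#' @param eu_unweighted,eu_weighted Named lists (by term) of pan-European
#'   `trend_series`.
#' @param first_case_date First-case date of the combined dataset (the
#'   earliest first case across countries).
#' @param exact_cap Passed to [mann_whitney()].
#' @return Tibble: `term`, `dataset`, `shift`, `status`, `p_value`, and a
#'   per-term `discordant` flag.
#' @export
pandemic_shift_table <- function(eu_unweighted, eu_weighted,
                                 first_case_date, exact_cap = 400) {
  one <- function(series, dataset) {
    sp <- split_by_first_case(series, first_case_date)
    if (!sp$valid)
      return(tibble::tibble(term = series$term, dataset = dataset,
                            shift = "invalid", status = "invalid",
                            p_value = NA_real_))
    mw <- mann_whitney(sp$during, sp$outside, exact_cap = exact_cap)
    st <- classify(mw$p)
    shift <- if (st %in% sig_statuses) mw$direction else "none"
    tibble::tibble(term = series$term, dataset = dataset, shift = shift,
                   status = st, p_value = mw$p)
  }
  terms <- union(names(eu_unweighted), names(eu_weighted))
  out <- dplyr::bind_rows(lapply(terms, function(tr) dplyr::bind_rows(
    one(eu_unweighted[[tr]], "unweighted"),
    one(eu_weighted[[tr]], "weighted"))))
  disc <- dplyr::summarise(dplyr::group_by(out, .data$term),
                           discordant = dplyr::n_distinct(.data$shift) > 1,
                           .groups = "drop")
  dplyr::left_join(out, disc, by = "term")
}
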