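#' Configuration of a synthetic search-interest world
#'
#' Defines a fully synthetic "world" with known ground truth: hidden weekly
#' query proportions per (country, language, term variant), countermeasure
#' calendars, first-case dates and case curves, plus the observation model
#' that turns hidden proportions into Google-Trends-like integer series.
#'
#' Defaults mirror the study design the package emulates: a weekly axis of
#' 235 ISO weeks (January 2017 - June 2021), nine replicate acquisitions per
#' series, and integer 0-100 normalization of every observed series.
#' Sampling defaults (`n_total = 2e5` weekly queries, `subsample_fraction =
#' 0.25`, baseline proportion `2e-3`) are chosen so that replicate-level
#' noise is clearly visible but consolidation recovers the signal — the
#' regime the consolidation chain is designed for.
#'
#' @param countries Named list: country code -> list with `population`,
#'   `languages` (named native-speaker shares), and optionally `first_case`
#'   (`Date`). A missing `first_case` defaults to 2020-03-02.
#' @param terms Named list: term-group name -> list with `variants` (named
#'   list: language -> character vector of variant spellings), `baseline`
#'   (list `level`, `trend`, `seasonal_amplitude`, `phase`), and `effects`
#'   (named numeric: measure -> multiplicative shift while active; 1 = null).
#' @param measures Named list: measure name -> list `start_lag` (days after
#'   first case) and `duration` (days), or an explicit calendar tibble via
#'   `calendar`.
#' @param calendar Optional explicit calendar tibble (`country`, `measure`,
#'   `start`, `end`, half-open) overriding `measures`.
#' @param period_start,period_end Half-open analysis period; start must be
#'   a Monday.
#' @param n_replicates Replicate acquisitions per series (default 9).
#' @param subsample_fraction Fraction of weekly traffic each acquisition
#'   samples, in (0, 1].
#' @param n_total Weekly total query volume before subsampling.
#' @param low_volume_threshold Observed proportion below which (for every
#'   week) the series is censored to all-zero, emulating empty Google
#'   Trends results for rare queries. Default 0 (off).
#' @param seed Master seed; every stochastic draw derives its stream from
#'   it and the identity of the series.
#' @return A `world_config` list.
#' @export
world_config <- function(countries = NULL, terms = NULL, measures = NULL,
                         calendar = NULL,
                         period_start = as.Date("2017-01-02"),
                         period_end = as.Date("2021-07-05"),
                         n_replicates = 9, subsample_fraction = 0.25,
                         n_total = 2e5, low_volume_threshold = 0,
                         seed = 1L) {
  countries <- countries %||% list(
    DE = list(population = 83166711, languages = c(de = 100)),
    PT = list(population = 10295909, languages = c(pt = 100)),
    BE = list(population = 11522440,
              languages = c(nl = 59, fr = 40, de = 1)))
  terms <- terms %||% list(
    anxiety = list(
      variants = list(de = c("angst"), pt = c("ansiedade"),
                      nl = c("angst"), fr = c("anxiete", "angoisse")),
      baseline = list(level = 2e-3, trend = 0.1,
                      seasonal_amplitude = 0.1, phase = 0),
      effects = c(lockdown = 1.5)),
    psychotherapy = list(
      variants = list(de = c("psychotherapie"), pt = c("psicoterapia"),
                      nl = c("psychotherapie"), fr = c("psychotherapie")),
      baseline = list(level = 1e-3, trend = 0,
                      seasonal_amplitude = 0.05, phase = 1),
      effects = c(lockdown = 1.3)))
  measures <- measures %||% list(
    lockdown = list(start_lag = 21, duration = 180))
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop("subsample_fraction must lie in (0, 1]")
  if (n_total < 1) stop("n_total must be >= 1")
  for (tr in terms)
    if (!is.null(tr$effects) && any(tr$effects <= 0))
      stop("effects must be positive multipliers")
  structure(list(countries = countries, terms = terms, measures = measures,
                 calendar = calendar,
                 period_start = as.Date(period_start),
                 period_end = as.Date(period_end),
                 n_replicates = as.integer(n_replicates),
                 subsample_fraction = subsample_fraction,
                 n_total = n_total,
                 low_volume_threshold = low_volume_threshold,
                 seed = as.integer(seed)),
            class = "world_config")
}

#' Generate the ground truth of a synthetic world
#'
#' Deterministic given the configuration: hidden weekly query proportions
#' per (country, language, term variant) follow a smooth baseline (level,
#' linear trend, annual seasonality) multiplied, while a measure is active,
#' by that (term, measure) effect — prorated by the fraction of the week's
#' days the measure covers. Measure intervals start a configured lag after
#' the country's first confirmed case, so the first case always precedes
#' every activation.
#'
#' @param config A [world_config()].
#' @return List: `truth` (tibble `country`, `language`, `term`, `variant`,
#'   `week_start`, `p`), `calendar` (tibble `country`, `measure`, `start`,
#'   `end`), `first_cases` (tibble `country`, `first_case_date`), `cases`
#'   (tibble `country`, `date`, `cases`), and `weeks` (the week axis).
#' @export
generate_world <- function(config) {
  weeks <- period_weeks(config$period_start, config$period_end)
  if (length(weeks) < 2) stop("degenerate period: fewer than 2 weeks")
  nW <- length(weeks)
  t01 <- (seq_len(nW) - 1) / (nW - 1)

  first_cases <- tibble::tibble(
    country = names(config$countries),
    first_case_date = as.Date(vapply(config$countries, function(ci)
      as.character(ci$first_case %||% as.Date("2020-03-02")), character(1))))

  calendar <- config$calendar
  if (is.null(calendar)) {
    rows <- list()
    for (cty in names(config$countries)) {
      fc <- first_cases$first_case_date[first_cases$country == cty]
      for (m in names(config$measures)) {
        mm <- config$measures[[m]]
        s <- fc + mm$start_lag
        rows[[length(rows) + 1L]] <- tibble::tibble(
          country = cty, measure = m, start = s, end = s + mm$duration)
      }
    }
    calendar <- dplyr::bind_rows(rows) %||%
      tibble::tibble(country = character(), measure = character(),
                     start = as.Date(character()), end = as.Date(character()))
  }

  truth_rows <- list()
  for (cty in names(config$countries)) {
    langs <- names(config$countries[[cty]]$languages)
    for (tg in names(config$terms)) {
      term <- config$terms[[tg]]
      b <- term$baseline
      base_p <- b$level * (1 + b$trend * t01) *
        (1 + b$seasonal_amplitude *
           sin(2 * pi * seq_len(nW) / 52.18 + b$phase))
      mult <- rep(1, nW)
      for (m in names(term$effects)) {
        eff <- term$effects[[m]]
        cal <- calendar[calendar$country == cty & calendar$measure == m, ,
                        drop = FALSE]
        if (nrow(cal) == 0) next
        frac <- week_coverage_days(weeks, cal$start, cal$end) / 7
        mult <- mult * (1 + (eff - 1) * frac)
      }
      p <- base_p * mult
      for (lg in langs) {
        variants <- term$variants[[lg]]
        if (is.null(variants)) next
        for (v in variants) {
          truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
            country = cty, language = lg, term = tg, variant = v,
            week_start = weeks, p = p)
        }
      }
    }
  }
  truth <- dplyr::bind_rows(truth_rows)

  days <- seq(config$period_start, config$period_end - 1L, by = "1 day")
  cases_rows <- lapply(names(config$countries), function(cty) {
    fc <- first_cases$first_case_date[first_cases$country == cty]
    td <- as.numeric(days - fc)
    cases <- 1000 * exp(-((td - 45) / 25)^2) + 1500 * exp(-((td - 260) / 40)^2)
    cases[td < 0] <- 0
    tibble::tibble(country = cty, date = days, cases = round(cases))
  })

  list(truth = truth, calendar = calendar, first_cases = first_cases,
       cases = dplyr::bind_rows(cases_rows), weeks = weeks)
}

#' Observe a synthetic world the way Google Trends would
#'
#' Each replicate acquisition draws, for every week, a binomial count of
#' matching queries out of `round(subsample_fraction * n_total)` sampled
#' queries with the hidden weekly proportion as success probability,
#' divides by the weekly subsample total, rescales the series so its
#' maximum is 100, and rounds to integers. Replicates differ only by their
#' RNG stream, mirroring a fresh daily sample. If every weekly observed
#' proportion falls below `low_volume_threshold` (or the series never hits
#' a positive count) the all-zero "empty" series is emitted.
#'
#' @param world Output of [generate_world()].
#' @param config The [world_config()] used to generate it.
#' @param period_start,period_end Optional sub-period to observe (a
#'   nine-month window, for instance); the series is normalized to 100
#'   within the observed period, as a real per-window query would be.
#' @param replicate_ids Replicate labels (default `"r1" ... "rk"` with
#'   `k = config$n_replicates`).
#' @return Raw-observation tibble (`country`, `language`, `term`, i.e. the
#'   variant-level term identifier `term|variant`, `week_start`, `value`,
#'   `replicate_id`) passing [validate_raw_trends()].
#' @export
sample_trends <- function(world, config, period_start = NULL,
                          period_end = NULL,
                          replicate_ids = paste0("r", seq_len(config$n_replicates))) {
  ps <- as.Date(period_start %||% config$period_start)
  pe <- as.Date(period_end %||% config$period_end)
  total <- max(1L, as.integer(round(config$subsample_fraction * config$n_total)))
  keys <- unique(world$truth[, c("country", "language", "term", "variant")])
  out <- vector("list", nrow(keys) * length(replicate_ids))
  k <- 0L
  for (i in seq_len(nrow(keys))) {
    kk <- keys[i, ]
    tr <- world$truth[world$truth$country == kk$country &
                        world$truth$language == kk$language &
                        world$truth$term == kk$term &
                        world$truth$variant == kk$variant, , drop = FALSE]
    sel <- tr$week_start >= ps & tr$week_start < pe
    tr <- tr[sel, , drop = FALSE]
    if (nrow(tr) == 0) next
    for (rid in replicate_ids) {
      key <- paste(kk$country, kk$language, kk$term, kk$variant, rid,
                   format(ps), sep = "|")
      set.seed(derive_seed(config$seed, key))
      counts <- rbinom(nrow(tr), total, pmin(1, tr$p))
      prop <- counts / total
      if (max(prop) == 0 || all(prop < config$low_volume_threshold)) {
        value <- rep(0L, nrow(tr))
      } else {
        value <- as.integer(round_half_up(100 * prop / max(prop), 0))
      }
      k <- k + 1L
      out[[k]] <- tibble::tibble(
        country = kk$country, language = kk$language,
        term = paste(kk$term, kk$variant, sep = "|"),
        week_start = tr$week_start, value = value, replicate_id = rid)
    }
  }
  dplyr::bind_rows(out[seq_len(k)])
}

#' Minimal one-country screening world
#'
#' Convenience configuration for calibration studies: one country, one
#' term, one measure whose active interval covers the final
#' `weeks_during` weeks of the period exactly, leaving `weeks_outside`
#' comparison weeks. The hidden proportion is constant (no trend, no
#' seasonality), so with `effect = 1` the weekly observations are i.i.d.
#' under the null.
#'
#' @param effect Multiplicative shift of the hidden proportion while the
#'   measure is active (1 = null).
#' @param weeks_outside,weeks_during Weeks outside / during the measure.
#' @param n_replicates Replicates per acquisition.
#' @param level Baseline weekly query proportion.
#' @param seed Master seed.
#' @inheritParams world_config
#' @return A `world_config`.
#' @export
screen_config <- function(effect = 1, weeks_outside = 31, weeks_during = 30,
                          n_replicates = 3, level = 2e-3, seed = 1L,
                          n_total = 2e5, subsample_fraction = 0.25) {
  start <- as.Date("2019-06-03")                 # a Monday
  nW <- weeks_outside + weeks_during
  m_start <- start + 7L * weeks_outside
  world_config(
    countries = list(AA = list(population = 1e6, languages = c(en = 100),
                               first_case = start + 7L)),
    terms = list(term = list(
      variants = list(en = "term"),
      baseline = list(level = level, trend = 0, seasonal_amplitude = 0,
                      phase = 0),
      effects = c(measure = effect))),
    calendar = tibble::tibble(country = "AA", measure = "measure",
                              start = m_start, end = start + 7L * nW),
    period_start = start, period_end = start + 7L * nW,
    n_replicates = n_replicates, subsample_fraction = subsample_fraction,
    n_total = n_total, seed = seed)
}

#' Run the screening pipeline on one synthetic world
#'
#' Generates the world, observes it, consolidates the replicates, splits by
#' the measure calendar and screens with the Mann-Whitney test — the full
#' downstream path a real dataset would take. Used for type-I-error and
#' power calibration over many seeds.
#'
#' @param config A [world_config()] (typically [screen_config()]).
#' @return Triplet-result tibble, one row per (country, term, measure).
#' @export
screen_world <- function(config) {
  world <- generate_world(config)
  raw <- sample_trends(world, config)
  sets <- raw_to_replicate_sets(raw)
  series <- lapply(sets, merge_replicates)
  run_triplet_tests(series, world$calendar)
}
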