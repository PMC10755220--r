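#' Validate a pipeline run configuration
#'
#' @param config List with a `world` ([world_config()]) plus screening
#'   thresholds: `sig_level` (default 0.05), `very_sig_level` (default
#'   0.01, must be below `sig_level`), `coverage` (default 4/7),
#'   `exact_cap` (default 400), `use_windows` (default `TRUE`),
#'   `window_months` (default 9).
#' @return The completed configuration, with defaults filled in.
#' @export
validate_run_config <- function(config) {
  if (is.null(config$world) || !inherits(config$world, "world_config"))
    stop("config$world must be a world_config")
  config$sig_level <- config$sig_level %||% 0.05
  config$very_sig_level <- config$very_sig_level %||% 0.01
  config$coverage <- config$coverage %||% 4 / 7
  config$exact_cap <- config$exact_cap %||% 400
  config$use_windows <- config$use_windows %||% TRUE
  config$window_months <- config$window_months %||% 9
  for (th in c("sig_level", "very_sig_level"))
    if (config[[th]] <= 0 || config[[th]] >= 1)
      stop(th, " must lie in (0, 1)")
  if (config$very_sig_level >= config$sig_level)
    stop("very_sig_level must be below sig_level")
  if (config$coverage <= 0 || config$coverage > 1)
    stop("coverage must lie in (0, 1]")
  config
}

#' Consolidate raw observations into variant-level series
#'
#' Runs [consolidate_series()] for every (country, language, term-variant)
#' in a raw-observation table, optionally recalibrating against
#' short-window observations.
#'
#' @param raw Full-period raw-observation tibble.
#' @param raw_windows Optional list of per-window raw-observation tibbles
#'   tiling the full period.
#' @return Named list of consolidated `trend_series`, keyed
#'   `country|language|term`.
#' @export
consolidate_raw <- function(raw, raw_windows = NULL) {
  sets <- raw_to_replicate_sets(raw)
  win_sets <- lapply(raw_windows %||% list(), raw_to_replicate_sets)
  lapply(stats::setNames(names(sets), names(sets)), function(key) {
    wreps <- lapply(win_sets, function(ws) ws[[key]])
    wreps <- Filter(Negate(is.null), wreps)
    consolidate_series(sets[[key]], if (length(wreps)) wreps else NULL)
  })
}

#' Merge variant-level series into country-term series
#'
#' Applies the synonym average ([merge_variants()]) and the
#' native-speaker-weighted language merge ([merge_languages()]) to a set of
#' variant-level consolidated series.
#'
#' @param variant_series Named list from [consolidate_raw()]; each series'
#'   `term` is `termgroup|variant`.
#' @param countries Named list of country definitions carrying `languages`
#'   shares (as in [world_config()]).
#' @return Named list of country-term `trend_series`, keyed `country|term`.
#' @export
merge_country_terms <- function(variant_series, countries) {
  meta <- do.call(rbind, lapply(variant_series, function(s) {
    parts <- strsplit(s$term, "|", fixed = TRUE)[[1]]
    data.frame(country = s$country, language = s$language,
               term = parts[1], stringsAsFactors = FALSE)
  }))
  out <- list()
  for (cty in unique(meta$country)) {
    shares <- countries[[cty]]$languages
    for (tg in unique(meta$term[meta$country == cty])) {
      by_lang <- list()
      for (lg in unique(meta$language[meta$country == cty &
                                        meta$term == tg])) {
        idx <- which(meta$country == cty & meta$language == lg &
                       meta$term == tg)
        merged <- merge_variants(variant_series[idx], term = tg)
        by_lang[[lg]] <- merged
      }
      w <- normalize_language_weights(shares[names(by_lang)])
      out[[paste(cty, tg, sep = "|")]] <- merge_languages(by_lang, w)
    }
  }
  out
}

#' Run the full screening pipeline on a synthetic world
#'
#' One-command end-to-end run: simulate, consolidate (including nine-month
#' window recalibration when enabled), screen every (country, term,
#' measure) triplet, aggregate into per-measure tables and the pre/post
#' first-case shift table, and write all artifacts as CSV plus a JSON
#' manifest. Deterministic given the world seed; rerunning with the same
#' configuration reproduces byte-identical outputs.
#'
#' @param config Run configuration (see [validate_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the consolidated series, triplet results,
#'   aggregate tables, shift table and output paths.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_run_config(config)
  wc <- config$world
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  world <- generate_world(wc)
  raw <- sample_trends(world, wc)
  write_trends_csv(raw, file.path(out_dir, "raw_trends.csv"))

  raw_windows <- NULL
  if (isTRUE(config$use_windows)) {
    wins <- make_windows(wc$period_start, wc$period_end,
                         config$window_months)
    if (nrow(wins) > 1) {
      raw_windows <- lapply(seq_len(nrow(wins)), function(i)
        sample_trends(world, wc, wins$start[i], wins$end[i]))
    }
  }

  variant_series <- consolidate_raw(raw, raw_windows)
  country_series <- merge_country_terms(variant_series, wc$countries)

  populations <- vapply(wc$countries, function(ci) ci$population, numeric(1))
  terms <- unique(vapply(country_series, function(s) s$term, character(1)))
  eu_weighted <- eu_unweighted <- list()
  for (tg in terms) {
    per_cty <- Filter(function(s) s$term == tg, country_series)
    names(per_cty) <- vapply(per_cty, function(s) s$country, character(1))
    eu_weighted[[tg]] <- combine_countries(per_cty, populations)
    eu_unweighted[[tg]] <- combine_countries(
      per_cty, stats::setNames(rep(1, length(per_cty)), names(per_cty)))
  }

  triplets <- run_triplet_tests(country_series, world$calendar,
                                coverage = config$coverage,
                                exact_cap = config$exact_cap)
  tables <- aggregate_tables(triplets, populations)
  shift <- pandemic_shift_table(eu_unweighted, eu_weighted,
                                min(world$first_cases$first_case_date),
                                exact_cap = config$exact_cap)

  cons_tbl <- dplyr::bind_rows(c(lapply(country_series, as_tibble_series),
                                 lapply(eu_weighted, as_tibble_series)))
  write_table(cons_tbl, file.path(out_dir, "consolidated.csv"))
  write_table(triplets, file.path(out_dir, "triplets.csv"))
  write_table(tables$by_term, file.path(out_dir, "table_by_term.csv"))
  write_table(tables$dominating, file.path(out_dir, "dominating.csv"))
  write_table(shift, file.path(out_dir, "shift_table.csv"))

  manifest <- list(
    package = "trendscreen",
    version = as.character(utils::packageVersion("trendscreen")),
    seed = wc$seed,
    n_countries = length(wc$countries),
    n_terms = length(wc$terms),
    n_replicates = wc$n_replicates,
    period = c(format(wc$period_start), format(wc$period_end)),
    thresholds = list(sig = config$sig_level, very = config$very_sig_level,
                      coverage = config$coverage,
                      exact_cap = config$exact_cap),
    use_windows = isTRUE(config$use_windows) && !is.null(raw_windows))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(world = world, country_series = country_series,
                 eu_unweighted = eu_unweighted, eu_weighted = eu_weighted,
                 triplets = triplets, tables = tables, shift = shift,
                 out_dir = out_dir))
}
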