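#!/usr/bin/env Rscript
# Stage 2: consolidate the raw replicate observations — weekly averaging,
# rescaling to 100.0 (unrounded), nine-month window recalibration, synonym
# averaging, native-speaker-weighted language merging, and the two
# pan-European combinations (population-weighted and unweighted).

source("analysis/00_config.R")
cfg <- demo_world()

raw <- read_trends_csv(file.path(data_dir, "raw_trends.csv"))
win_files <- sort(list.files(data_dir, "^raw_window_", full.names = TRUE))
raw_windows <- lapply(win_files, read_trends_csv)

variant_series <- consolidate_raw(raw, raw_windows)
message(sprintf("consolidated %d variant series (windows: %d)",
                length(variant_series), length(raw_windows)))

country_series <- merge_country_terms(variant_series, cfg$countries)

# how much did replicate averaging de-noise? compare against ground truth
truth <- readr::read_csv(file.path(data_dir, "truth.csv"),
                         show_col_types = FALSE)
mae <- sapply(names(country_series)[1], function(key) {
  s <- country_series[[key]]
  tt <- truth[truth$country == s$country & truth$term == s$term, ]
  tt <- tt[tt$variant == tt$variant[1] & tt$language == tt$language[1], ]
  mean(abs(s$value - 100 * tt$p / max(tt$p)))
})
message(sprintf("mean abs. deviation from normalized truth (%s): %.2f",
                names(mae)[1], mae[[1]]))

pops <- read_population_csv(file.path(data_dir, "populations.csv"))
terms <- unique(vapply(country_series, `[[`, character(1), "term"))
eu_w <- eu_u <- list()
for (tg in terms) {
  per_cty <- Filter(function(s) s$term == tg, country_series)
  names(per_cty) <- vapply(per_cty, `[[`, character(1), "country")
  eu_w[[tg]] <- combine_countries(per_cty, pops)
  eu_u[[tg]] <- combine_countries(
    per_cty, stats::setNames(rep(1, length(per_cty)), names(per_cty)))
}

write_table(dplyr::bind_rows(lapply(country_series, as_tibble_series)),
            file.path(res_dir, "consolidated_countries.csv"))
write_table(dplyr::bind_rows(lapply(eu_u, as_tibble_series)),
            file.path(res_dir, "eu_unweighted.csv"))
write_table(dplyr::bind_rows(lapply(eu_w, as_tibble_series)),
            file.path(res_dir, "eu_weighted.csv"))
message("stage 2 done: consolidated series written")
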