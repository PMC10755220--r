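#!/usr/bin/env Rscript
# Stage 3: Mann-Whitney screening of every (country, term, countermeasure)
# triplet — weekly search volume during vs. outside the measure's active
# intervals, two significance tiers (p <= 0.05, p < 0.01), invalid where
# the measure or series gives no comparison.

source("analysis/00_config.R")

series <- series_from_table(
  read_table_csv(file.path(res_dir, "consolidated_countries.csv")))
calendar <- read_measure_calendar(file.path(data_dir, "calendar.csv"))

triplets <- run_triplet_tests(series, calendar)
write_table(triplets, file.path(res_dir, "triplets.csv"))

n_sig <- sum(triplets$status %in% c("significant", "very_significant"))
message(sprintf("screened %d triplets: %d (very) significant, %d invalid",
                nrow(triplets), n_sig,
                sum(triplets$status == "invalid")))
message("stage 3 done: triplets.csv written")
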