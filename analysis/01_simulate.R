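#!/usr/bin/env Rscript
# Stage 1: generate the synthetic world and observe it as Google Trends
# would — one full-period acquisition plus one per nine-month window, each
# repeated n_replicates times with a fresh sampling stream. Writes the raw
# observation tables, the countermeasure calendar, case curves and
# populations under results/data/.

source("analysis/00_config.R")
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- demo_world()
world <- generate_world(cfg)

message(sprintf("world: %d countries, %d term variants, %d weeks",
                length(cfg$countries),
                nrow(unique(world$truth[, c("country", "language",
                                            "term", "variant")])),
                length(world$weeks)))

raw <- sample_trends(world, cfg)
write_trends_csv(raw, file.path(data_dir, "raw_trends.csv"))

wins <- demo_windows(cfg)
for (i in seq_len(nrow(wins))) {
  w <- sample_trends(world, cfg, wins$start[i], wins$end[i])
  write_trends_csv(w, file.path(data_dir, sprintf("raw_window_%02d.csv", i)))
}
message(sprintf("observed %d replicate series over %d windows",
                length(unique(raw$replicate_id)), nrow(wins)))

# calendar in the inclusive-end CSV dialect the reader ingests
cal <- world$calendar
readr::write_csv(
  tibble::tibble(country = cal$country, measure = cal$measure,
                 date_start = cal$start, date_end = cal$end - 1L),
  file.path(data_dir, "calendar.csv"))
readr::write_csv(world$cases, file.path(data_dir, "cases.csv"))
readr::write_csv(world$first_cases, file.path(data_dir, "first_cases.csv"))
readr::write_csv(
  tibble::tibble(country = names(cfg$countries),
                 population = vapply(cfg$countries, `[[`, numeric(1),
                                     "population")),
  file.path(data_dir, "populations.csv"))

# normalized ground truth, for the de-noising check in stage 2
readr::write_csv(world$truth, file.path(data_dir, "truth.csv"))
message("stage 1 done: raw observations written")
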