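#!/usr/bin/env Rscript
# Stage 4: roll triplet results up into the headline tables — per-measure
# percentages of countries with (very) significant change, unweighted and
# population-weighted, the dominating search terms, and the pre/post
# first-case shift classification of the two pan-European datasets.

source("analysis/00_config.R")

triplets <- read_table_csv(file.path(res_dir, "triplets.csv"))
pops <- read_population_csv(file.path(data_dir, "populations.csv"))

tabs <- aggregate_tables(triplets, pops)
write_table(tabs$by_term, file.path(res_dir, "table_by_term.csv"))
write_table(tabs$dominating, file.path(res_dir, "dominating.csv"))

for (m in unique(tabs$dominating$measure)) {
  d <- tabs$dominating[tabs$dominating$measure == m, ]
  message(sprintf("measure '%s': dominating effect '%s' (%g%% of countries)",
                  m, d$term[1], d$pct[1]))
}

eu_u <- series_from_table(read_table_csv(file.path(res_dir, "eu_unweighted.csv")))
eu_w <- series_from_table(read_table_csv(file.path(res_dir, "eu_weighted.csv")))
names(eu_u) <- vapply(eu_u, `[[`, character(1), "term")
names(eu_w) <- vapply(eu_w, `[[`, character(1), "term")
first_cases <- readr::read_csv(file.path(data_dir, "first_cases.csv"),
                               show_col_types = FALSE)

shift <- pandemic_shift_table(eu_u, eu_w, min(first_cases$first_case_date))
write_table(shift, file.path(res_dir, "shift_table.csv"))
for (tg in unique(shift$term)) {
  d <- shift[shift$term == tg, ]
  message(sprintf("term '%s': %s (unweighted), %s (weighted)%s", tg,
                  d$shift[d$dataset == "unweighted"],
                  d$shift[d$dataset == "weighted"],
                  if (any(d$discordant)) " [discordant]" else ""))
}
message("stage 4 done: aggregate tables written")
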