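#!/usr/bin/env Rscript
# Stage 6: series panels — consolidated weekly search volume with its
# uncertainty band, the 9-week moving average, the scaled case curve and
# the countermeasure bars.

source("analysis/00_config.R")
fig_dir <- file.path(res_dir, "figures")
dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)

series <- series_from_table(
  read_table_csv(file.path(res_dir, "consolidated_countries.csv")))
calendar <- read_measure_calendar(file.path(data_dir, "calendar.csv"))
cases <- read_cases_csv(file.path(data_dir, "cases.csv"))

for (s in series) {
  p <- plot_series(s, calendar, cases)
  f <- file.path(fig_dir, sprintf("%s_%s.png", s$country, s$term))
  ggplot2::ggsave(f, p, width = 9, height = 4, dpi = 120)
  message("wrote ", f)
}
message("stage 6 done")
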