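# Shared configuration of the demo analysis: a three-country synthetic
# world (one multilingual), two search-term groups with known injected
# effects, one countermeasure, observed five times per series. All drivers
# source this file so that every stage sees the same world.

library(trendscreen)

res_dir <- "results"
data_dir <- file.path(res_dir, "data")

demo_world <- function() {
  world_config(
    countries = list(
      DE = list(population = 83166711, languages = c(de = 100),
                first_case = as.Date("2020-01-27")),
      PT = list(population = 10295909, languages = c(pt = 100),
                first_case = as.Date("2020-03-02")),
      BE = list(population = 11522440,
                languages = c(nl = 59, fr = 40, de = 1),
                first_case = as.Date("2020-02-03"))),
    terms = list(
      anxiety = list(
        variants = list(de = "angst", pt = "ansiedade",
                        nl = "angst", fr = c("anxiete", "angoisse")),
        baseline = list(level = 2e-3, trend = 0.1,
                        seasonal_amplitude = 0.1, phase = 0),
        effects = c(lockdown = 2.0)),
      psychotherapy = list(
        variants = list(de = "psychotherapie", pt = "psicoterapia",
                        nl = "psychotherapie", fr = "psychotherapie"),
        baseline = list(level = 1e-3, trend = 0,
                        seasonal_amplitude = 0.05, phase = 1),
        effects = c(lockdown = 1.3))),
    measures = list(lockdown = list(start_lag = 21, duration = 180)),
    period_start = as.Date("2019-01-07"),
    period_end = as.Date("2021-07-05"),
    n_replicates = 5, seed = 7)
}

demo_windows <- function(cfg) make_windows(cfg$period_start, cfg$period_end,
                                           months = 9)
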