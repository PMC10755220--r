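# trendscreen

Infodemiological screening of weekly relative-search-volume (RSV) time
series against calendars of pandemic countermeasures.

Google-Trends-style RSV exports are noisy measurements: each export is
built from an undisclosed, daily-changing subsample of all searches,
normalized so the queried window's maximum is 100, and rounded to an
integer. `trendscreen` is for researchers who want to ask, on top of such
data, "did search interest in *anxiety* change while *teleworking
recommendations* were in force?" — across many countries, languages and
countermeasures, with honest handling of the measurement error.

The package implements:

* **Consolidation** — repeated exports of one series are averaged per week
  and rescaled so the mean series peaks at exactly 100.0 (unrounded), with
  a per-week uncertainty estimate `sd_w = c * sqrt(s_w^2/n + 1/12)`
  combining replicate scatter and the ±0.5 rounding error. Nine-month
  query windows are recalibrated onto the global series (window max →
  global max over the same interval) and stitched; synonyms average
  unweighted; languages merge with native-speaker-share weights; countries
  combine into population-weighted and unweighted pan-European datasets.
* **Screening** — for each (country, term, countermeasure) triplet, a
  two-sided Mann–Whitney U test compares weekly values during vs. outside
  the measure's active intervals (a week is "during" when ≥ 4/7 of its
  days are covered). Small problems (`n1·n2 ≤ 400`) use the exact
  permutation distribution of the midrank sum (valid under ties); larger
  ones a tie- and continuity-corrected normal approximation. Tiers:
  `p ≤ 0.05` significant, `p < 0.01` very significant; triplets without a
  usable comparison are *invalid*, not errors.
* **Aggregation** — per (measure, term) the percentage of valid countries
  with a (very) significant change, unweighted (integer) and
  population-weighted (one decimal); any-term and all-pairs roll-ups;
  dominating-term ranking; and a pre/post first-confirmed-case shift table
  for the two pan-European datasets.
* **A synthetic world generator** — hidden weekly query proportions with
  configurable (term, measure) effects, observed through binomial
  subsampling + max-100 normalization + integer rounding, so the whole
  pipeline runs and calibrates without any network access.

## Worked example

Three replicate exports disagree; consolidation averages, rescales and
quantifies the disagreement, and the screen compares the lockdown weeks
against the rest:

```r
library(trendscreen)

weeks <- period_weeks("2020-01-06", "2020-03-02")   # 8 ISO weeks
reps <- list(
  trend_series("DE", "anxiety", weeks, c(20, 25, 18, 22, 60, 80, 100, 90)),
  trend_series("DE", "anxiety", weeks, c(25, 20, 20, 25, 55, 85, 95, 100)),
  trend_series("DE", "anxiety", weeks, c(18, 22, 25, 20, 65, 75, 100, 85)))
cons <- merge_replicates(reps)
round(cons$value, 2)
#> [1]  21.36  22.71  21.36  22.71  61.02  81.36 100.00  93.22
round(cons$sd, 2)     # replicate scatter + rounding floor, on the 0-100 scale
#> [1] 2.14 1.51 2.14 1.51 2.95 2.95 1.72 4.49

cal <- tibble::tibble(country = "DE", measure = "lockdown",
                      start = as.Date("2020-02-03"),
                      end   = as.Date("2020-03-02"))
test_triplet(cons, cal, "lockdown")
#> # A tibble: 1 × 8
#>   country term    measure  status      p_value direction n_during n_outside
#>   <chr>   <chr>   <chr>    <chr>         <dbl> <chr>        <int>     <int>
#> 1 DE      anxiety lockdown significant  0.0286 increase         4         4
```

The four lockdown weeks rank strictly above the four pre-lockdown weeks
(U = 16, the maximum), and the exact two-sided p over all 70 group
assignments is 2/70 ≈ 0.029: a significant increase.

Aggregating a 27-country screen — 17 significant, 10 not — gives the
percentage of affected countries, equal-weighted and population-weighted:

```r
st   <- read_table_csv(system.file("extdata", "teleworking_anxiety_status.csv",
                                   package = "trendscreen"))
pops <- read_population_csv(system.file("extdata",
                                        "populations_eu2020_reconstructed.csv",
                                        package = "trendscreen"))
country_fraction(st)$pct              # 17 of 27 countries
#> [1] 63
weighted_country_fraction(st, pops)$pct   # share of the population affected
#> [1] 74.1
```

## The analysis workflow

`analysis/` holds the end-to-end demo as numbered drivers over the package
(run from the repository root, in order):

| script | what it does | writes |
|---|---|---|
| `01_simulate.R` | synthetic 3-country world, 5 replicate acquisitions, 9-month windows | `results/data/` |
| `02_consolidate.R` | full consolidation chain incl. window recalibration, language merge, EU datasets | `results/*.csv` |
| `03_screen.R` | Mann–Whitney screen of every triplet | `results/triplets.csv` |
| `04_aggregate.R` | percentage tables, dominating effects, pre/post shift table | `results/table_by_term.csv`, … |
| `05_calibration.R` | null false-positive rate and power on minimal worlds | `results/calibration.csv` |
| `06_figures.R` | series panels: values, sd band, 9-week moving average, cases, measure bars | `results/figures/` |

`run_pipeline()` performs the same chain as a single call.

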