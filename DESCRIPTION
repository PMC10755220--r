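Package: trendscreen
Title: Consolidation and Countermeasure Screening of Search-Interest Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for infodemiological screening of weekly relative
    search-volume (RSV) time series against calendars of pandemic
    countermeasures. Implements replicate consolidation of noisy,
    integer-rounded RSV exports (weekly averaging, rescaling to 100,
    nine-month window recalibration, synonym and multilingual merging,
    population-weighted pan-European combination, with per-week
    uncertainty estimates), Mann-Whitney U screening of search frequency
    during versus outside countermeasure periods (exact permutation
    distribution under ties, or tie- and continuity-corrected normal
    approximation), two-level significance aggregation across countries
    (unweighted and population-weighted percentages, dominating-effect
    ranking, pre/post first-case shift tables), and a fully synthetic
    world generator with known ground truth for calibration and power
    studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
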