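---
title: "Consolidating and screening search-interest time series against countermeasure calendars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consolidating and screening search-interest time series against countermeasure calendars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trendscreen)
```

## The problem

Relative search volume (RSV), as exported by Google Trends, is an appealing
proxy for population-level interest in a topic — including health-related
distress — but it is a difficult measurement. Each export is (i) based on an
undisclosed subsample of all searches, drawn afresh every day, (ii)
normalized so that the maximum over the queried window is 100, and (iii)
rounded to an integer. Two downloads of the "same" series therefore
disagree, low-volume weeks carry large relative rounding error, and rare
queries come back as an all-zero ("empty") series.

`trendscreen` implements a complete screening pipeline on top of such data:

1. **Consolidation** of repeated noisy exports into one calibrated weekly
   series per (country, term group), with a per-week uncertainty estimate;
2. **Screening** of weekly search frequency during vs. outside each
   countermeasure's active period with a Mann-Whitney U test;
3. **Aggregation** of per-country outcomes into percentages of countries
   (population-weighted and unweighted) showing a (very) significant
   change, dominating-term rankings, and a pre/post first-case shift table;
4. A **synthetic world generator** with known ground truth, so every stage
   is testable without network access and the screening's error rates can
   be measured.

## Consolidation model

For one country and search-term variant, let $x_{w,r}$ be the integer RSV
of week $w$ in replicate export $r = 1,\dots,n$. Consolidation computes the
weekly mean $\bar x_w$ and rescales the averaged series to
$v_w = 100\,\bar x_w / \max_w \bar x_w$ — unrounded, so a consolidated
series attains its maximum of exactly 100.0 unless it is all-zero. The
per-week standard deviation combines replicate scatter with the variance of
a uniform $\pm 0.5$ rounding error:

$$\widehat{sd}_w = c\,\sqrt{s_w^2/n + 1/12},$$

with $s_w^2$ the across-replicate sample variance, $c$ the rescaling
factor, and the $1/12$ floor surviving even for identical replicates. With
one replicate the scatter term is taken as zero; the estimate is then the
rounding floor alone.

Short nine-month query windows resolve low-volume periods better than the
full-period query, because normalization happens within the window. They
are recalibrated by mapping the window's maximum onto the maximum of the
global averaged series over the same interval (factor
$\max(\text{global})/\max(\text{window})$, both over the window) and then
stitched; the windows must tile the full period exactly. On noiseless input
this recalibration reproduces the global series to machine precision, which
the test suite asserts.

Synonym variants within a language are averaged without weighting.
Languages within a multilingual country are merged with weights
proportional to native-speaker shares; shares are renormalized over the
official languages (residual population speaking none of them natively is
dropped). Countries combine into two pan-European datasets: weighted by
population size and unweighted (uniform weights), both produced by the same
operation.

Three conventions in this chain were genuinely open and are fixed as
follows:

* **Empty vs. zero.** An all-zero raw series is flagged *empty* (the
  response Google returns below its volume threshold) and is excluded from
  synonym averages; in weighted merges the weights renormalize over the
  non-empty components, so a language without volume does not deflate a
  multilingual country's signal. A zero *value* inside a live series is
  ordinary data.
* **Rescaling the combined dataset.** Whether the pan-European combination
  is rescaled after weighting is unspecified in the source procedure; we
  rescale to max 100.0 for consistency with every other series
  (`rescale = FALSE` preserves the raw weighted mean). Rank-based
  screening is unaffected either way.
* **Reported weights.** Merge weights are kept at full precision; reports
  round to three decimals with largest-remainder rounding, which keeps the
  printed weights summing to exactly 1.000 and resolves exact rounding
  ties (e.g. shares 93/3 give 0.96875/0.03125, printed 0.969/0.031).
* **Uncertainty propagation** through the linear merges assumes
  independence (root-sum-of-squares of weighted sds); this is an
  approximation, adequate for the plotted bands, and is not used by the
  screening statistics.

## Screening model

For each triplet (country, term group, countermeasure) the consolidated
weekly values are split into *during* weeks — at least 4/7 of the week's
days inside an active interval of the measure (configurable) — and all
remaining *outside* weeks. Because measures activate in several disjoint
intervals, the default comparison group contains every non-active week
(before, between, and after activations); a `before_only` mode restricts it
to weeks before the first activation for users who prefer a strict
pre-measure baseline. The triplet is *invalid* — an outcome, not an error —
when the measure never applies in that country, when either group is empty,
or when the series is empty.

The two groups are compared with a two-sided Mann-Whitney U test. For
`n1 * n2 <= 400` the permutation distribution of the midrank sum is
computed exactly by a subset-sum dynamic programme — valid under ties and
identical to brute-force enumeration of all $\binom{n_1+n_2}{n_1}$ group
assignments, which the test suite checks to $10^{-12}$. Larger problems use
the normal approximation with tie correction and a 0.5 continuity
correction; exact and approximate p agree within 0.01 from group sizes of
about a dozen. Integer RSV data is heavily tied, which is why the exact
path enumerates the midrank-sum distribution rather than the tie-free U
recursion. Effect direction is the sign of the difference of group medians,
consistent with a rank test; ties give direction "none".

Significance uses two tiers: $p \le 0.05$ *significant*, $p < 0.01$ *very
significant*. No multiple-testing correction is applied in the default
screening — the procedure is an exploratory screen across triplets, and
corrected variants can be layered on the returned p-values (e.g.
`p.adjust`) without changing anything else.

## Aggregation

For one (measure, term), the headline number is the percentage of countries
with a significant-or-better outcome among countries with a *valid* test;
invalid countries leave the denominator entirely, so a 17-of-27 split
reports 63% even when 32 countries were queried. The population-weighted
variant replaces country counts by population sums (reported to one
decimal; unweighted table percentages round to integers, half away from
zero). Two term-independent roll-ups exist, because both readings of
"change in any search term" are useful: *any-term* (a country counts once
if any term fires) and *all-pairs* (fraction over valid country × term
pairs); both are always computed and labelled. Terms are ranked per measure
by their unweighted percentage — the top term is the measure's *dominating
effect* — with ties broken by the weighted percentage, then alphabetically,
and flagged.

The pre/post comparison splits each pan-European series at the first
confirmed case (the earliest across countries; the first-case week itself
belongs to the pandemic side) and classifies each term as
increase/decrease/none per dataset, flagging terms whose weighted and
unweighted datasets disagree.

## The synthetic world

The generator emulates the structure of the real inputs, with known ground
truth. Hidden weekly query proportions follow a smooth baseline (level,
linear trend, annual sinusoid); while a measure is active the proportion is
multiplied by the configured (term, measure) effect, prorated by the
fraction of the week's days covered. Observation mimics the RSV mechanism:
each replicate draws weekly binomial counts out of
`round(subsample_fraction * n_total)` sampled queries, divides by the
subsample total, rescales the series maximum to 100 and rounds to integers;
an optional low-volume threshold censors rare series to all-zero.
Replicates differ only by their RNG stream, and every stream is keyed by
the identity of the series (country, language, variant, replicate, window),
so enlarging the world never perturbs existing draws.

Default study conditions: a 235-week axis (January 2017 - June 2021,
weeks keyed by their Monday), nine replicate acquisitions, nine-month
recalibration windows. Where the emulated design fixes no value we chose
once: baseline proportions around $10^{-3}$–$2\times10^{-3}$ (a plausibly
rare health query), `n_total = 2e5` weekly queries with a 25% subsample —
a regime where single replicates are visibly noisy (weekly coefficient of
variation of order 10%) yet nine-replicate consolidation recovers the
signal, which is the situation the consolidation chain exists for.

What the generator does **not** model: Google's true (undisclosed)
sampler, linguistic content, behavioural dynamics of searching, and serial
correlation of search interest beyond the smooth baseline. Passing tests
therefore demonstrate that the pipeline's arithmetic and its statistical
calibration are correct under a binomial observation model — not that real
RSV data satisfies that model.

## Calibration results computed by this package

Calibration uses minimal one-country worlds (constant baseline, one
measure covering the final 30 of 61 weeks, so the null weeks are i.i.d.).
With a null effect (1.0) the full pipeline — generate, observe, consolidate,
split, test — flags significance at close to the nominal rate: 0.051 over
1000 seeds in the shipped calibration run (the acceptance suite requires
$0.05 \pm 0.02$ over 1000 seeds). With a doubled search frequency
(effect 2.0, nine replicates, 30/31-week groups) the screen flagged every
one of 200 seeds, always with direction "increase". The slight conservatism
of the rank test on tied integer data is expected from the continuity
correction and discreteness.

Problem sizes throughout the test-suite and the analysis drivers (61-130
week worlds, 3-9 replicates, a few hundred to a thousand seeds) were chosen
as the smallest sizes at which these properties are statistically
resolvable.

## Degenerate inputs and numerical conventions

* Dates are ISO-8601; all intervals are half-open `[start, end)`, and ECDC
  exports' inclusive end dates gain one day on ingest. Weeks are keyed by
  their Monday; ingest rejects week keys that are not Mondays rather than
  guessing how partial weeks were truncated.
* All-zero replicate sets consolidate to the all-zero empty series; an
  all-zero window passes through window recalibration unscaled and
  flagged.
* Identical samples in both groups give $p = 1$ with direction "none";
  a zero tie-corrected variance does the same.
* Percentages are rounded half away from zero (integer for unweighted
  tables, one decimal for weighted), with three internal decimals.
* Week-axis alignment in every merge is by calendar week key, never by
  position; misaligned axes are errors, not warnings.

## Limitations

The screening is deliberately a rank-test screen: it ignores serial
correlation, seasonality confounding, and simultaneity of countermeasures,
and it estimates association, not causal effect. Interrupted-time-series
regression or autocorrelation-robust tests are out of scope. The
population table shipped with the package is a reconstruction from
Eurostat 2020 figures and is documented as such; users with the exact
table of their own study population should supply it via
`read_population_csv()`.
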