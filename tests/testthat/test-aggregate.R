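triplet_rows <- function(statuses, terms = "t", measure = "m") {
  tibble::tibble(country = paste0("C", seq_along(statuses)),
                 term = terms, measure = measure, status = statuses)
}

test_that("country fractions exclude invalid countries from the denominator", {
  st <- c(rep("significant", 10), rep("very_significant", 7),
          rep("not_significant", 10))
  cf <- country_fraction(triplet_rows(st))
  expect_equal(cf$pct, 63)            # 17 of 27
  expect_equal(cf$n_valid, 27L)
  expect_equal(cf$n_sig, 17L)

  cf_inv <- country_fraction(triplet_rows(c(st, rep("invalid", 5))))
  expect_equal(cf_inv$pct, cf$pct)    # invalid countries never move the pct
  expect_equal(cf_inv$n_valid, 27L)

  expect_equal(country_fraction(triplet_rows(rep("not_significant", 4)))$pct, 0)
  expect_equal(country_fraction(triplet_rows(rep("significant", 4)))$pct, 100)
  expect_false(country_fraction(triplet_rows(rep("invalid", 3)))$valid)
})

test_that("population weighting reduces to the simple fraction under equal populations", {
  st <- triplet_rows(c("significant", "not_significant", "very_significant",
                       "not_significant"))
  pops_eq <- stats::setNames(rep(7, 4), st$country)
  expect_equal(weighted_country_fraction(st, pops_eq)$pct_raw,
               country_fraction(st)$pct_raw, tolerance = 1e-9)

  two <- triplet_rows(c("significant", "not_significant"))
  expect_equal(weighted_country_fraction(
    two, c(C1 = 9, C2 = 1))$pct, 90.0)
  expect_error(weighted_country_fraction(two, c(C1 = 9)), "missing population")
})

test_that("term roll-ups: any-term dominates each per-term pct; all-pairs counts pairs", {
  tr <- dplyr::bind_rows(
    triplet_rows(c("significant", "not_significant", "invalid",
                   "not_significant"), terms = "a"),
    triplet_rows(c("not_significant", "very_significant", "significant",
                   "not_significant"), terms = "b"))
  any_t <- any_term_fraction(tr, "any-term")
  expect_equal(any_t$pct, 75)          # 3 of 4 countries hit in >= 1 term
  all_p <- any_term_fraction(tr, "all-pairs")
  expect_equal(all_p$pct_raw, 100 * 3 / 7)
  for (term in c("a", "b")) {
    cf <- country_fraction(tr[tr$term == term, ])
    expect_gte(any_t$pct_raw, cf$pct_raw)
  }
  expect_equal(any_term_fraction(triplet_rows(rep("not_significant", 3)),
                                 "any-term")$pct, 0)
  # 3 of 8 valid pairs -> 37.5%
  tr8 <- dplyr::bind_rows(
    triplet_rows(c("significant", "significant", "not_significant",
                   "not_significant"), terms = "a"),
    triplet_rows(c("very_significant", "not_significant", "not_significant",
                   "not_significant"), terms = "b"))
  expect_equal(any_term_fraction(tr8, "all-pairs")$pct, 37.5)
})

test_that("dominating-effect ranking orders terms by pct with deterministic tie-breaks", {
  one <- dominating_effect(tibble::tibble(term = "anxiety", pct = 40))
  expect_equal(one$term, "anxiety")

  two <- dominating_effect(tibble::tibble(
    term = c("panic attack", "anxiety"), pct = c(40, 63)))
  expect_equal(two$term, c("anxiety", "panic attack"))
  expect_false(any(two$tie))

  tie <- dominating_effect(tibble::tibble(
    term = c("b-term", "a-term"), pct = c(50, 50),
    pct_weighted = c(40, 40)))
  expect_equal(tie$term, c("a-term", "b-term"))   # alphabetical on full tie
  expect_true(all(tie$tie))
  tie_w <- dominating_effect(tibble::tibble(
    term = c("a-term", "b-term"), pct = c(50, 50),
    pct_weighted = c(10, 60)))
  expect_equal(tie_w$term[1], "b-term")           # weighted pct breaks tie
})

test_that("flipping a country to significant never decreases any percentage", {
  set.seed(41)
  for (i in 1:10) {
    st <- sample(c("significant", "not_significant", "invalid"), 12,
                 replace = TRUE, prob = c(0.3, 0.5, 0.2))
    tr <- triplet_rows(st)
    flip <- which(st == "not_significant")
    if (!length(flip)) next
    tr2 <- tr; tr2$status[flip[1]] <- "significant"
    pops <- stats::setNames(runif(12, 1, 50), tr$country)
    expect_gte(country_fraction(tr2)$pct_raw, country_fraction(tr)$pct_raw)
    expect_gte(weighted_country_fraction(tr2, pops)$pct_raw,
               weighted_country_fraction(tr, pops)$pct_raw)
  }
})

test_that("aggregate tables carry per-term rows plus ANY and ALL-PAIRS roll-ups", {
  tr <- dplyr::bind_rows(
    triplet_rows(c("significant", "not_significant", "invalid"), terms = "a"),
    triplet_rows(c("very_significant", "significant", "not_significant"),
                 terms = "b"))
  pops <- stats::setNames(c(10, 20, 30), paste0("C", 1:3))
  tabs <- aggregate_tables(tr, pops)
  expect_setequal(unique(tabs$by_term$term), c("a", "b", "ANY", "ALL-PAIRS"))
  row_a <- tabs$by_term[tabs$by_term$term == "a", ]
  expect_equal(row_a$pct_unweighted, 50)
  expect_equal(row_a$n_valid, 2L)
  expect_equal(tabs$dominating$term[1], "b")
})

test_that("pre/post first-case shifts classify direction per dataset and flag discordance", {
  set.seed(42)
  wk <- make_weeks(120)
  fc <- wk[61]
  up <- trend_series("EU", "up", wk,
                     round(c(rpois(60, 15), rpois(60, 40))))
  null1 <- trend_series("EU", "flat", wk, round(rpois(120, 25)))
  down_w <- trend_series("EU", "mixed", wk,
                         round(c(rpois(60, 40), rpois(60, 15))))
  null2 <- trend_series("EU", "mixed", wk, round(rpois(120, 25)))
  tab <- pandemic_shift_table(
    eu_unweighted = list(up = up, flat = null1, mixed = down_w),
    eu_weighted = list(up = up, flat = null1, mixed = null2),
    first_case_date = fc)
  get <- function(term, ds) tab$shift[tab$term == term & tab$dataset == ds]
  expect_equal(get("up", "unweighted"), "increase")
  expect_equal(get("up", "weighted"), "increase")
  expect_equal(get("flat", "unweighted"), "none")
  expect_equal(get("mixed", "unweighted"), "decrease")
  expect_equal(get("mixed", "weighted"), "none")
  expect_true(all(tab$discordant[tab$term == "mixed"]))
  expect_false(any(tab$discordant[tab$term == "up"]))
})

test_that("a shift confined to the most populous country surfaces only in the weighted dataset", {
  wk <- make_weeks(120)
  set.seed(43)
  # moderate shift (about 1 sd) in the big country: dominant in the
  # population-weighted dataset, diluted ~1/sqrt(k) among 20 equal peers
  big <- trend_series("BG1", "t", wk, round(c(rpois(60, 20), rpois(60, 25))))
  smalls <- lapply(1:20, function(i)
    trend_series(paste0("S", i), "t", wk, round(rpois(120, 20))))
  series <- c(list(BG1 = big), stats::setNames(smalls, paste0("S", 1:20)))
  pops <- c(BG1 = 1000, stats::setNames(rep(1, 20), paste0("S", 1:20)))
  eq <- stats::setNames(rep(1, 21), names(series))
  ew <- list(t = combine_countries(series, pops))
  eu <- list(t = combine_countries(series, eq))
  tab <- pandemic_shift_table(eu, ew, wk[61])
  expect_equal(tab$shift[tab$dataset == "weighted"], "increase")
  expect_equal(tab$shift[tab$dataset == "unweighted"], "none")
})
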