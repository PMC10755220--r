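test_that("exact Mann-Whitney matches hand-computed and library values", {
  out <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(out$U, 0)
  expect_equal(out$p, 1 / 3)          # 2 of the 6 assignments as extreme
  expect_equal(out$method, "exact")
  expect_equal(out$direction, "decrease")

  # independent cross-check against stats::wilcox.test on tie-free data
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
    expect_equal(mann_whitney(x, y)$p,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("exact enumeration handles ties identically to brute force", {
  set.seed(32)
  for (i in 1:40) {
    x <- sample(0:5, sample(2:6, 1), replace = TRUE)
    y <- sample(0:5, sample(2:6, 1), replace = TRUE)
    if (length(unique(c(x, y))) == 1L) next
    expect_equal(mann_whitney(x, y)$p, mw_bruteforce_p(x, y),
                 tolerance = 1e-12,
                 info = paste(paste(x, collapse = ","), "vs",
                              paste(y, collapse = ",")))
  }
})

test_that("identical samples are degenerate: p = 1, no direction", {
  out <- mann_whitney(rep(4, 5), rep(4, 7))
  expect_equal(out$p, 1)
  expect_equal(out$direction, "none")
})

test_that("U statistics of the two groups sum to n1*n2 on tie-free data", {
  set.seed(33)
  for (i in 1:20) {
    x <- rnorm(sample(2:10, 1)); y <- rnorm(sample(2:10, 1))
    u1 <- mann_whitney(x, y)$U
    u2 <- mann_whitney(y, x)$U
    expect_equal(u1 + u2, length(x) * length(y))
  }
})

test_that("the two-sided p is symmetric under group swap and direction flips", {
  set.seed(34)
  for (cap in c(400, 0)) {   # exact and normal-approximation paths
    x <- rnorm(15); y <- rnorm(15) + 0.8
    a <- mann_whitney(x, y, exact_cap = cap)
    b <- mann_whitney(y, x, exact_cap = cap)
    expect_equal(a$p, b$p, tolerance = 1e-12)
    expect_true(a$direction == "decrease" && b$direction == "increase")
  }
})

test_that("normal approximation tracks the exact p for moderate samples", {
  set.seed(35)
  for (i in 1:25) {
    n1 <- sample(12:16, 1); n2 <- sample(12:16, 1)
    x <- rnorm(n1); y <- rnorm(n2) + runif(1, -1, 1)
    pe <- mann_whitney(x, y, exact_cap = 400)$p
    pa <- mann_whitney(x, y, exact_cap = 0)$p
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("significance tiers follow the <=0.05 / <0.01 boundaries", {
  expect_equal(classify(0.05), "significant")       # boundary is inclusive
  expect_equal(classify(0.0099), "very_significant")
  expect_equal(classify(0.009), "very_significant")
  expect_equal(classify(0.01), "significant")
  expect_equal(classify(0.051), "not_significant")
  expect_equal(classify(NA), "invalid")
  expect_equal(classify(NULL), "invalid")
  expect_error(classify(1.5), "\\[0, 1\\]")
})

test_that("measure splits assign weeks by day coverage and flag invalid cases", {
  wk <- make_weeks(30)
  s <- make_series(seq(10, 100, length.out = 30))
  cal <- calendar_for_weeks("DE", "lockdown", wk, 10, 20)
  sp <- split_by_measure(s, cal, "lockdown")
  expect_true(sp$valid)
  expect_equal(sp$n_during, 11L)
  expect_equal(sp$n_outside, 19L)

  # a week with only 3 of 7 days covered stays outside at threshold 4/7
  cal_part <- tibble::tibble(country = "DE", measure = "m",
                             start = wk[5] + 4L, end = wk[7])
  sp2 <- split_by_measure(s, cal_part, "m")
  expect_equal(sp2$n_during, 1L)   # week 6 fully covered; week 5 only 3 days

  expect_false(split_by_measure(s, cal, "unknown-measure")$valid)
  all_cal <- calendar_for_weeks("DE", "always", wk, 1, 30)
  expect_false(split_by_measure(s, all_cal, "always")$valid)  # no outside
  empty <- make_series(rep(0, 30))
  expect_false(split_by_measure(empty, cal, "lockdown")$valid)
})

test_that("before-only mode drops weeks between activations from the comparison group", {
  wk <- make_weeks(30)
  s <- make_series(rep(c(10, 90), 15))
  cal <- tibble::tibble(country = "DE", measure = "m",
                        start = wk[c(5, 15)], end = wk[c(8, 20)] + 7L)
  sp_all <- split_by_measure(s, cal, "m")
  sp_before <- split_by_measure(s, cal, "m", before_only = TRUE)
  expect_equal(sp_all$n_during, sp_before$n_during)
  expect_equal(sp_before$n_outside, 4L)            # weeks 1-4 only
  expect_gt(sp_all$n_outside, sp_before$n_outside)
})

test_that("first-case splits put the first-case week into the pandemic group", {
  wk <- make_weeks(235, start = as.Date("2017-01-02"))
  s <- trend_series("DE", "t", wk, seq_along(wk))
  sp <- split_by_first_case(s, wk[160] + 3)   # mid-week date in week 160
  expect_true(sp$valid)
  expect_equal(sp$n_outside, 159L)
  expect_equal(sp$n_during, 76L)
  expect_false(split_by_first_case(s, as.Date("2016-12-01"))$valid)
  expect_false(split_by_first_case(s, max(wk) + 7L)$valid)
})

test_that("an upward shift after the first case is detected as a significant increase", {
  set.seed(36)
  wk <- make_weeks(100)
  vals <- round(pmin(100, c(rpois(60, 20), rpois(40, 40))))
  s <- trend_series("DE", "t", wk, vals)
  sp <- split_by_first_case(s, wk[61])
  mw <- mann_whitney(sp$during, sp$outside)
  expect_equal(classify(mw$p), "very_significant")
  expect_equal(mw$direction, "increase")
})

test_that("triplet testing rolls split, test and classification into one row", {
  wk <- make_weeks(30)
  s <- make_series(c(rep(10, 15), rep(60, 15)), country = "AT",
                   term = "anxiety")
  cal <- calendar_for_weeks("AT", "lockdown", wk, 16, 30)
  row <- test_triplet(s, cal, "lockdown")
  expect_equal(row$status, classify(row$p_value))
  expect_equal(row$direction, "increase")
  expect_equal(row$n_during + row$n_outside, 30L)

  inv <- test_triplet(s, cal, "not-a-measure")
  expect_equal(inv$status, "invalid")
  expect_true(is.na(inv$p_value))
})
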