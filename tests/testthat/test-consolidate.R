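test_that("replicate merging averages weekly and rescales the mean to exactly 100", {
  s <- merge_replicates(list(make_series(c(50, 100))))
  expect_equal(s$value, c(50, 100))

  m <- merge_replicates(list(make_series(c(100, 50)), make_series(c(80, 100))))
  expect_equal(m$value, c(100, 250 / 3))   # means (90, 75) scaled by 100/90
  expect_equal(m$n_replicates, 2L)
  expect_false(m$empty)

  z <- merge_replicates(list(make_series(c(0, 0)), make_series(c(0, 0))))
  expect_true(z$empty)
  expect_equal(z$value, c(0, 0))
})

test_that("misaligned replicate week axes are rejected", {
  expect_error(
    merge_replicates(list(make_series(c(1, 2)),
                          make_series(c(1, 2), start = monday0 + 7))),
    "week axis")
})

test_that("uncertainty combines replicate scatter with the rounding floor", {
  m1 <- matrix(c(5, 5, 5), ncol = 1)
  expect_equal(estimate_uncertainty(m1, scale = 1),
               rep(sqrt(1 / 12), 3))                  # rounding floor only
  m2 <- matrix(c(49, 51), nrow = 1)
  expect_equal(estimate_uncertainty(m2, scale = 1), sqrt(2 / 2 + 1 / 12))
  expect_equal(estimate_uncertainty(m2, scale = 2),
               2 * estimate_uncertainty(m2, scale = 1))  # linear in scale
})

test_that("window rescaling maps the window maximum onto the global maximum", {
  g <- make_series(c(20, 40, 80, 100, 60, 10))
  w_id <- make_series(g$value[3:4], start = g$week_start[3])
  expect_equal(window_rescale(g, w_id)$value, g$value[3:4])  # factor 1

  w <- make_series(c(25, 100), start = g$week_start[3])      # window max 100
  out <- window_rescale(g, w)                                # global max 100
  expect_equal(out$value, c(25, 100))
  w2 <- make_series(c(25, 100), start = g$week_start[5])     # global max 60
  expect_equal(window_rescale(g, w2)$value, c(15, 60))

  wz <- make_series(c(0, 0), start = g$week_start[3])
  outz <- window_rescale(g, wz)
  expect_equal(outz$value, c(0, 0))
  expect_true(isTRUE(attr(outz, "unscaled")))
})

test_that("stitching requires an exact tiling and reproduces the axis", {
  g <- make_series(c(10, 20, 100, 50, 40, 30))
  w1 <- make_series(g$value[1:3], start = g$week_start[1])
  w2 <- make_series(g$value[4:6], start = g$week_start[4])
  out <- stitch_windows(list(w2, w1), g)   # order must not matter
  expect_equal(out$value, g$value)
  expect_equal(out$week_start, g$week_start)

  single <- stitch_windows(list(make_series(g$value)), g)
  expect_equal(single$value, g$value)

  overlap <- make_series(g$value[3:6], start = g$week_start[3])
  expect_error(stitch_windows(list(w1, overlap), g), "tile")
  gap <- make_series(g$value[5:6], start = g$week_start[5])
  expect_error(stitch_windows(list(w1, gap), g), "tile")
})

test_that("noiseless window recalibration reproduces the global series exactly", {
  set.seed(3)
  vals <- round(runif(24, 0, 90), 3); vals[13] <- 100
  g <- make_series(vals)
  # windows observed with arbitrary private normalizations
  pieces <- list(1:8, 9:16, 17:24)
  factors <- c(3.7, 0.21, 12)
  windows <- Map(function(idx, f)
    make_series(vals[idx] * f, start = g$week_start[idx[1]]), pieces, factors)
  scaled <- lapply(windows, function(w) window_rescale(g, w))
  out <- stitch_windows(scaled, g)
  expect_equal(out$value, g$value, tolerance = 1e-12)
})

test_that("synonym variants average unweighted, excluding empty series", {
  a <- make_series(c(100, 0)); b <- make_series(c(0, 100))
  expect_equal(merge_variants(list(a, b))$value, c(50, 50))
  expect_equal(merge_variants(list(a, a))$value, a$value)
  z <- make_series(c(0, 0))
  expect_equal(merge_variants(list(a, z))$value, a$value)  # empty excluded
  expect_true(merge_variants(list(z, z))$empty)
})

test_that("language merging weights by native-speaker share and renormalizes over live languages", {
  wk <- make_weeks(3)
  # zero-valued but live series (a real observation of zero interest),
  # as opposed to the empty series Google returns for absent volume
  mk <- function(v, lg) trend_series("BE", "t", wk, rep(v, 3), language = lg,
                                     empty = FALSE)
  be <- normalize_language_weights(c(nl = 59, fr = 40, de = 1))
  out <- merge_languages(list(nl = mk(100, "nl"), fr = mk(0, "fr"),
                              de = mk(0, "de")), be)
  expect_equal(out$value, rep(59, 3))

  sym <- merge_languages(list(a = make_series(c(100, 0), language = "a"),
                              b = make_series(c(0, 100), language = "b")),
                         c(a = 0.5, b = 0.5))
  expect_equal(sym$value, c(50, 50))

  # an empty language drops out and weights renormalize over the rest
  mke <- function(lg) trend_series("BE", "t", wk, rep(0, 3), language = lg)
  ren <- merge_languages(list(nl = mk(80, "nl"), fr = mke("fr"),
                              de = mke("de")),
                         c(nl = 0.5, fr = 0.25, de = 0.25))
  expect_equal(ren$value[1], 80 * 1)  # nl alone is live (fr, de empty)

  one <- merge_languages(list(xx = make_series(c(10, 100), language = "xx")),
                         c(xx = 1))
  expect_equal(one$value, c(10, 100))
  expect_error(merge_languages(list(nl = mk(1, "nl")), c(fr = 1)),
               "lacks language")
})

test_that("country combination weights by population and rescales to 100", {
  a <- make_series(rep(100, 3), country = "A")
  b <- make_series(rep(0, 3), country = "B")
  out <- combine_countries(list(A = a, B = b), c(A = 3, B = 1))
  expect_equal(out$value, rep(100, 3))    # 75 before the max-100 rescale
  raw <- combine_countries(list(A = a, B = b), c(A = 3, B = 1),
                           rescale = FALSE)
  expect_equal(raw$value, rep(75, 3))
  expect_equal(out$country, "EU")

  eq <- combine_countries(list(A = a, B = a), c(A = 1, B = 1))
  expect_equal(eq$value, a$value)
  one <- combine_countries(list(A = a), c(A = 42))
  expect_equal(one$value, a$value)
  expect_error(combine_countries(list(A = a, B = b), c(A = 1)),
               "missing population")
})

test_that("consolidation is scale equivariant and permutation invariant", {
  set.seed(21)
  reps <- lapply(1:4, function(i) make_series(sample(0:100, 6, replace = TRUE)))
  base <- merge_replicates(reps)
  scaled <- merge_replicates(lapply(reps, function(s)
    make_series(s$value * 0.37)))
  expect_equal(scaled$value, base$value, tolerance = 1e-12)
  perm <- merge_replicates(reps[c(3, 1, 4, 2)])
  expect_equal(perm$value, base$value)
  expect_equal(perm$sd, base$sd)

  vars <- lapply(1:3, function(i) make_series(sample(0:100, 5, replace = TRUE)))
  expect_equal(merge_variants(vars[c(2, 3, 1)])$value,
               merge_variants(vars)$value)
})

test_that("consolidated error against ground truth falls with replicate count", {
  cfg <- screen_config(effect = 1, n_replicates = 9, seed = 99,
                       n_total = 5e4, subsample_fraction = 0.2)
  world <- generate_world(cfg)
  truth_p <- world$truth$p
  target <- 100 * truth_p / max(truth_p)
  mae <- sapply(c(1, 3, 9), function(n) {
    errs <- sapply(1:6, function(rep_seed) {
      cfg$seed <- 1000L + rep_seed
      raw <- sample_trends(world, cfg,
                           replicate_ids = paste0("r", seq_len(n)))
      cons <- merge_replicates(raw_to_replicate_sets(raw)[[1]])
      mean(abs(cons$value - target))
    })
    mean(errs)
  })
  expect_lt(mae[2], mae[1])
  expect_lt(mae[3], mae[2])
})
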