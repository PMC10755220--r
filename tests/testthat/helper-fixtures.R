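# Shared fixtures: tiny series builders and the brute-force Mann-Whitney
# oracle used to check the exact enumeration path.

monday0 <- as.Date("2020-01-06")

make_weeks <- function(n, start = monday0) start + 7L * (0:(n - 1L))

make_series <- function(values, country = "DE", term = "t",
                        language = NA_character_, sd = NULL,
                        start = monday0) {
  trend_series(country, term, make_weeks(length(values), start), values,
               language = language, sd = sd)
}

# Two-sided Mann-Whitney p by full enumeration of all group assignments:
# the fraction of size-n1 subsets of the pooled sample whose U deviates
# from its null mean by at least the observed deviation. Independent of
# the package's dynamic-programming implementation.
mw_bruteforce_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  u_of <- function(idx) {
    xs <- pool[idx]; ys <- pool[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  mu <- n1 * n2 / 2
  obs_dev <- abs(u_of(seq_len(n1)) - mu)
  us <- apply(utils::combn(n, n1), 2, u_of)
  mean(abs(us - mu) >= obs_dev - 1e-12)
}

# Calendar tibble covering weeks [from, to] (1-based) of a weekly axis.
calendar_for_weeks <- function(country, measure, weeks, from, to) {
  tibble::tibble(country = country, measure = measure,
                 start = weeks[from], end = weeks[to] + 7L)
}

extdata <- function(f) system.file("extdata", f, package = "trendscreen")
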