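#' Merge replicate observations into one consolidated weekly series
#'
#' Google Trends draws a fresh sample of all searches each day, so repeated
#' queries of the same series disagree. Consolidation takes the per-week mean
#' across replicates and rescales the averaged series so its maximum is
#' exactly 100.0 (unrounded). An all-zero replicate set stays all-zero and is
#' flagged empty. A per-week standard deviation combining replicate scatter
#' and the \eqn{\pm 0.5} integer-rounding error accompanies the values.
#'
#' @param reps List of `trend_series` replicates sharing one week axis and
#'   metadata.
#' @return A consolidated `trend_series` with `sd` and `n_replicates` set.
#' @export
merge_replicates <- function(reps) {
  if (length(reps) < 1L) stop("need at least one replicate")
  ax <- shared_week_axis(reps)
  m <- vapply(reps, function(s) s$value, numeric(length(ax)))
  m <- matrix(m, nrow = length(ax))
  mu <- rowMeans(m)
  mx <- max(mu)
  scale <- if (mx > 0) 100 / mx else 1
  sdw <- estimate_uncertainty(m, scale = scale)
  proto <- reps[[1]]
  trend_series(proto$country, proto$term, ax, mu * scale,
               language = proto$language, sd = sdw,
               n_replicates = length(reps), empty = mx == 0)
}

#' Per-week uncertainty of a consolidated series
#'
#' The estimated standard deviation at each week combines the
#' across-replicate sampling scatter with the variance of a uniform
#' \eqn{\pm 0.5} rounding error:
#' \deqn{sd_w = c \sqrt{s_w^2 / n + 1/12}}
#' where \eqn{s_w^2} is the sample variance across the \eqn{n} replicates at
#' week \eqn{w} and \eqn{c} the rescaling factor applied to the mean series.
#' With a single replicate the scatter term is taken as zero and only the
#' rounding floor remains.
#'
#' @param m Matrix of raw replicate values, weeks in rows.
#' @param scale Multiplicative factor applied to the averaged series.
#' @return Numeric vector of per-week standard deviations.
#' @export
estimate_uncertainty <- function(m, scale = 1) {
  m <- as.matrix(m)
  n <- ncol(m)
  s2 <- if (n == 1L) rep(0, nrow(m)) else apply(m, 1, var)
  scale * sqrt(s2 / n + 1 / 12)
}

#' Recalibrate a short-window series against the global series
#'
#' Nine-month query windows carry finer normalization resolution than the
#' full-period query; to place them on the global scale, the maximum of the
#' averaged window series is mapped onto the maximum of the global averaged
#' series over the same interval: values are multiplied by
#' `max(global over interval) / max(window over interval)`.
#'
#' @param global Consolidated full-period `trend_series`.
#' @param window Consolidated short-window `trend_series`.
#' @param start,end Half-open date interval of the window (defaults to the
#'   window's own span).
#' @return The rescaled window series; an all-zero window is passed through
#'   unscaled with attribute `unscaled = TRUE`.
#' @export
window_rescale <- function(global, window, start = NULL, end = NULL) {
  start <- as.Date(start %||% min(window$week_start))
  end <- as.Date(end %||% (max(window$week_start) + 7L))
  g <- series_window(global, start, end)
  w <- series_window(window, start, end)
  if (length(w) != length(window) || any(w$week_start != window$week_start))
    stop("interval must cover exactly the window series' weeks")
  wmax <- max(w$value)
  if (wmax == 0) {
    out <- window
    attr(out, "unscaled") <- TRUE
    return(out)
  }
  factor <- max(g$value) / wmax
  trend_series(window$country, window$term, window$week_start,
               window$value * factor, language = window$language,
               sd = if (is.null(window$sd)) NULL else window$sd * factor,
               n_replicates = window$n_replicates, empty = window$empty)
}

#' Stitch rescaled windows into one full-period series
#'
#' The rescaled short-window series must tile the global period exactly
#' (no gap, no overlap); their concatenation on the global week axis is the
#' consolidated full-period series, with each window's uncertainty carried
#' through.
#'
#' @param windows List of rescaled window `trend_series`.
#' @param global The global consolidated series defining the week axis.
#' @return A `trend_series` over the global period.
#' @export
stitch_windows <- function(windows, global) {
  o <- order(vapply(windows, function(w) min(w$week_start), numeric(1)))
  windows <- windows[o]
  weeks <- do.call(c, lapply(windows, function(w) w$week_start))
  if (length(weeks) != length(global$week_start) ||
      any(weeks != global$week_start))
    stop("windows must tile the global period without gap or overlap")
  vals <- do.call(c, lapply(windows, function(w) w$value))
  sds <- lapply(windows, function(w) w$sd)
  sdv <- if (any(vapply(sds, is.null, logical(1)))) NULL else do.call(c, sds)
  trend_series(global$country, global$term, global$week_start, vals,
               language = global$language, sd = sdv,
               n_replicates = global$n_replicates, empty = all(vals == 0))
}

#' Average synonym variants within one language
#'
#' Linguistic varieties of one search term (synonyms, declensions) within a
#' language are averaged without weighting. Empty (all-zero) variants are
#' excluded from the mean; if all variants are empty the result is empty.
#'
#' @param series_list List of per-variant consolidated `trend_series` sharing
#'   country, language, and week axis.
#' @param term Name for the merged term group (default: first variant's term).
#' @return A merged `trend_series`.
#' @export
merge_variants <- function(series_list, term = NULL) {
  ax <- shared_week_axis(series_list)
  term <- term %||% series_list[[1]]$term
  proto <- series_list[[1]]
  live <- Filter(function(s) !s$empty, series_list)
  if (length(live) == 0L) {
    return(trend_series(proto$country, term, ax, rep(0, length(ax)),
                        language = proto$language,
                        sd = rep(0, length(ax)), empty = TRUE))
  }
  k <- length(live)
  vals <- Reduce(`+`, lapply(live, function(s) s$value)) / k
  sds <- lapply(live, function(s) s$sd %||% rep(0, length(ax)))
  sdv <- sqrt(Reduce(`+`, lapply(sds, function(s) s^2))) / k
  trend_series(proto$country, term, ax, vals, language = proto$language,
               sd = sdv,
               n_replicates = min(vapply(live, function(s) s$n_replicates,
                                         integer(1))))
}

#' Merge per-language series with native-speaker weights
#'
#' Multilingual countries are merged as a weighted sum of the per-language
#' series, weights proportional to native-speaker shares
#' ([normalize_language_weights()]). Weights are renormalized over the
#' non-empty languages so that a language with no search volume does not
#' deflate the merged signal.
#'
#' @param series_by_language Named list (by language code) of consolidated
#'   `trend_series`.
#' @param weighting Output of [language_weighting()], or a named weight
#'   vector covering every supplied language.
#' @return Country-level merged `trend_series` (language `NA`).
#' @export
merge_languages <- function(series_by_language, weighting) {
  w <- if (is.list(weighting) && !is.null(weighting$weights))
    weighting$weights else weighting
  langs <- names(series_by_language)
  if (length(langs) == 1L && (is.null(w) || length(w) == 0)) {
    w <- stats::setNames(1, langs)
  }
  miss <- setdiff(langs, names(w))
  if (length(miss)) stop("weighting lacks language(s): ",
                         paste(miss, collapse = ", "))
  ax <- shared_week_axis(series_by_language)
  proto <- series_by_language[[1]]
  live <- !vapply(series_by_language, function(s) s$empty, logical(1))
  if (!any(live)) {
    return(trend_series(proto$country, proto$term, ax, rep(0, length(ax)),
                        sd = rep(0, length(ax)), empty = TRUE))
  }
  wl <- w[langs][live]
  wl <- wl / sum(wl)
  vals <- Reduce(`+`, Map(function(s, wi) wi * s$value,
                          series_by_language[live], wl))
  sds <- Map(function(s, wi) (wi * (s$sd %||% rep(0, length(ax))))^2,
             series_by_language[live], wl)
  trend_series(proto$country, proto$term, ax, vals,
               sd = sqrt(Reduce(`+`, sds)),
               n_replicates = min(vapply(series_by_language[live],
                                         function(s) s$n_replicates,
                                         integer(1))))
}

#' Combine country series into a pan-European series
#'
#' Countries are combined as a weighted mean of their consolidated series,
#' weights proportional to population size (uniform populations give the
#' unweighted variant). By default the combined series is rescaled so its
#' maximum is 100.0, consistent with every other consolidated series;
#' `rescale = FALSE` preserves the raw weighted mean.
#'
#' @param series_by_country Named list (by country code) of consolidated
#'   `trend_series` sharing one week axis.
#' @param populations Named numeric vector covering every country supplied.
#' @param rescale Rescale the combined series to max 100 (default `TRUE`).
#' @return A `trend_series` with country `"EU"`.
#' @export
combine_countries <- function(series_by_country, populations, rescale = TRUE) {
  ctys <- names(series_by_country)
  miss <- setdiff(ctys, names(populations))
  if (length(miss)) stop("missing population for: ",
                         paste(miss, collapse = ", "))
  ax <- shared_week_axis(series_by_country)
  proto <- series_by_country[[1]]
  w <- populations[ctys] / sum(populations[ctys])
  vals <- Reduce(`+`, Map(function(s, wi) wi * s$value,
                          series_by_country, w))
  sdv <- sqrt(Reduce(`+`, Map(function(s, wi)
    (wi * (s$sd %||% rep(0, length(ax))))^2, series_by_country, w)))
  mx <- max(vals)
  scale <- if (rescale && mx > 0) 100 / mx else 1
  trend_series("EU", proto$term, ax, vals * scale, sd = sdv * scale,
               n_replicates = min(vapply(series_by_country,
                                         function(s) s$n_replicates,
                                         integer(1))),
               empty = mx == 0)
}

#' Split a period into calendar windows for recalibration
#'
#' @param start,end Half-open period `[start, end)`.
#' @param months Window length in calendar months (default 9, the
#'   recalibration window used for weekly RSV queries).
#' @return Tibble of half-open window intervals tiling the period.
#' @export
make_windows <- function(start, end, months = 9) {
  start <- as.Date(start); end <- as.Date(end)
  bounds <- seq(start, by = sprintf("%d months", months),
                length.out = ceiling(as.numeric(end - start) / 28) + 2)
  bounds <- c(bounds[bounds < end], end)
  tibble::tibble(start = utils::head(bounds, -1), end = bounds[-1])
}

#' Full consolidation chain for one replicate collection
#'
#' Runs the complete consolidation for one (country, language, term-variant):
#' the full-period replicates are averaged and rescaled to 100; each
#' short-window replicate set is averaged, recalibrated against the global
#' series ([window_rescale()]), and the windows are stitched back together.
#' Without window replicates the global consolidated series is returned.
#'
#' @param global_reps List of full-period replicate `trend_series`.
#' @param window_reps Optional list of per-window replicate lists, each
#'   tiling the global period.
#' @return Consolidated `trend_series`.
#' @export
consolidate_series <- function(global_reps, window_reps = NULL) {
  g <- merge_replicates(global_reps)
  if (is.null(window_reps) || length(window_reps) == 0L) return(g)
  scaled <- lapply(window_reps, function(reps)
    window_rescale(g, merge_replicates(reps)))
  stitch_windows(scaled, g)
}
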