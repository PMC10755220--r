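#' Centered moving average over a fixed number of weeks
#'
#' @param x Numeric vector.
#' @param window Odd window length in weeks; 9 weeks approximates the
#'   two-month smoothing used in the series panels.
#' @return Numeric vector with `NA` at the edges.
#' @export
moving_average <- function(x, window = 9) {
  if (window %% 2 == 0) stop("window must be odd (centered average)")
  as.numeric(stats::filter(x, rep(1 / window, window), sides = 2))
}

#' Plot a consolidated series with uncertainty, cases and measure bars
#'
#' One panel per series: the consolidated weekly values with their
#' uncertainty band (estimated standard deviation from sampling and
#' rounding), a centered 9-week (about two months) moving average, the
#' national case curve rescaled to the same 0-100 axis, and bars below the
#' axis marking when each countermeasure was active.
#'
#' @param series A consolidated `trend_series`.
#' @param calendar Optional measure-calendar tibble for the series'
#'   country.
#' @param cases Optional case tibble (`country`, `date`, `cases`).
#' @param ma_window Moving-average window in weeks (odd, default 9).
#' @return A `ggplot` object. An empty series yields a placeholder panel
#'   with a warning.
#' @export
plot_series <- function(series, calendar = NULL, cases = NULL,
                        ma_window = 9) {
  df <- as_tibble_series(series)
  df$sd[is.na(df$sd)] <- 0
  df$ma <- moving_average(df$value, ma_window)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$week_start))
  if (series$empty) {
    warning("empty series: plotting placeholder panel")
    return(p + ggplot2::annotate("text", x = mean(df$week_start), y = 50,
                                 label = "empty series") +
             ggplot2::ylim(0, 100) + ggplot2::theme_minimal() +
             ggplot2::labs(title = sprintf("%s - %s (no data)",
                                           series$country, series$term),
                           x = NULL, y = "relative search volume"))
  }
  if (!is.null(cases)) {
    cc <- cases[cases$country == series$country, , drop = FALSE]
    if (nrow(cc) > 0 && max(cc$cases) > 0) {
      cc$scaled <- 100 * cc$cases / max(cc$cases)
      p <- p + ggplot2::geom_area(data = cc,
                                  ggplot2::aes(x = .data$date,
                                               y = .data$scaled),
                                  fill = "grey40", alpha = 0.3)
    }
  }
  p <- p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(0, .data$value - .data$sd),
                                      ymax = pmin(100, .data$value + .data$sd)),
                         fill = "red", alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$value), colour = "red",
                       linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ma), colour = "black",
                       na.rm = TRUE)
  if (!is.null(calendar)) {
    cal <- calendar[calendar$country == series$country, , drop = FALSE]
    if (nrow(cal) > 0) {
      cal$y <- -5 * as.integer(factor(cal$measure))
      p <- p + ggplot2::geom_segment(
        data = cal,
        ggplot2::aes(x = .data$start, xend = .data$end,
                     y = .data$y, yend = .data$y),
        linewidth = 2, colour = "steelblue")
    }
  }
  p + ggplot2::theme_minimal() +
    ggplot2::labs(title = sprintf("%s - %s", series$country, series$term),
                  x = NULL, y = "relative search volume")
}
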