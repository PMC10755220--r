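#' Normalize native-speaker shares into merge weights
#'
#' Multilingual countries are merged with weights proportional to the share
#' of native speakers of each official language; residual population that
#' speaks no official language natively is dropped, so weights are the
#' shares renormalized to sum to one. For example, Cyprus's census shares of
#' 81% Greek and 1% Turkish give weights 0.988 and 0.012.
#'
#' @param shares Named numeric vector of raw percentage shares (need not sum
#'   to 100); all non-negative, at least one positive.
#' @return Named numeric vector of full-precision weights summing to 1.
#' @export
normalize_language_weights <- function(shares) {
  if (length(shares) == 0) stop("no language shares supplied")
  if (is.null(names(shares)) || any(!nzchar(names(shares))))
    stop("shares must be named by language")
  if (any(!is.finite(shares) | shares < 0))
    stop("shares must be finite and non-negative")
  tot <- sum(shares)
  if (tot <= 0) stop("all language shares are zero")
  shares / tot
}

#' Round weights for reporting, preserving the unit sum
#'
#' Reports print weights to three decimals. Independent rounding of each
#' weight can break the unit sum (and exact .5 ties are ambiguous), so
#' reported weights use largest-remainder rounding: floors first, then the
#' leftover thousandths go to the largest fractional remainders. This
#' reproduces published weightings such as 0.969/0.031 (an exact rounding
#' tie) and guarantees the printed weights sum to exactly 1.
#'
#' @param weights Full-precision weights summing to 1.
#' @param digits Decimal places in the report (default 3).
#' @return Named numeric vector of rounded weights summing to exactly 1.
#' @export
report_weights <- function(weights, digits = 3) {
  p <- 10^digits
  scaled <- weights * p
  fl <- floor(scaled)
  rem <- round(p - sum(fl))
  frac <- scaled - fl
  if (rem > 0) {
    give <- order(frac, decreasing = TRUE)[seq_len(rem)]
    fl[give] <- fl[give] + 1
  }
  fl / p
}

#' Language weighting for one country
#'
#' @param country ISO country code.
#' @param shares Named raw shares (see [normalize_language_weights()]).
#' @return List with `country`, `shares`, full-precision `weights`, and
#'   3-decimal `reported` weights.
#' @export
language_weighting <- function(country, shares) {
  w <- normalize_language_weights(shares)
  list(country = country, shares = shares, weights = w,
       reported = report_weights(w))
}
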