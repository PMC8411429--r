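#' Round half away from zero
#'
#' Commercial ("half-up") rounding at `digits` decimals, as used for
#' table-style percentage display; base R's `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge past binary-representation error before truncating
  trunc(abs(x) * scale + 0.5 + 1e-9) / scale * sign(x)
}

#' Percentage of a count pair, display-rounded
#'
#' Vectorized over paired numerators and denominators.
#'
#' @param numerator,denominator Counts with `0 <= numerator <= denominator`
#'   and positive denominators.
#' @param decimals Decimal places (half-up).
#' @return `100 * numerator / denominator`, rounded.
#' @examples
#' proportion_pct(1636, 8275, 2)  # 19.77
#' @export
proportion_pct <- function(numerator, denominator, decimals = 2) {
  if (any(denominator <= 0)) stop("denominator must be positive", call. = FALSE)
  if (any(numerator < 0) || any(numerator > denominator)) {
    stop("numerator must lie in [0, denominator]", call. = FALSE)
  }
  round_half_up(100 * numerator / denominator, decimals)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' One degree of freedom; continuity correction defaults to off, matching
#' the convention that the squared two-proportion z-statistic equals the
#' Pearson statistic.
#'
#' @param table 2x2 numeric matrix of non-negative counts (rows = groups,
#'   columns = outcome yes/no) with positive row and column totals.
#' @param continuity_correction Apply the Yates correction? Default `FALSE`.
#' @return A list: `statistic`, `p_value`, `df`.
#' @export
chisq_2x2 <- function(table, continuity_correction = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("chi-squared test undefined for an empty row or column margin",
         call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = continuity_correction))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value),
       df = unname(res$parameter))
}

#' Median and interquartile range
#'
#' Quartiles by linear interpolation between order statistics (the
#' inclusive method, `stats::quantile` type 7).
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric vector `c(median, q1, q3)`.
#' @examples
#' median_iqr(1:5)  # 3, 2, 4
#' @export
median_iqr <- function(values) {
  if (length(values) == 0) stop("cannot summarize an empty vector", call. = FALSE)
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}
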