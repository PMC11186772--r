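## Small numeric helpers shared across modules.

#' Centred rolling mean with truncated edges
#'
#' Window of width `k` (odd) centred on each position; at the edges the
#' window is truncated rather than padded, so a constant input is returned
#' unchanged.
#'
#' @param x Numeric vector (NAs ignored within windows).
#' @param k Odd window width.
#' @return Numeric vector of the same length.
#' @export
roll_mean <- function(x, k) {
  stopifnot(k %% 2 == 1)
  h <- (k - 1L) %/% 2L
  n <- length(x)
  ok <- !is.na(x)
  xs <- ifelse(ok, x, 0)
  cs <- c(0, cumsum(xs))
  cn <- c(0, cumsum(as.numeric(ok)))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  tot <- cs[hi + 1L] - cs[lo]
  cnt <- cn[hi + 1L] - cn[lo]
  out <- tot / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Quantile bins with stable tie-breaking
#'
#' Ranks non-missing values (ties broken by input order) and splits them into
#' `n_bins` near-equal groups, so a larger value never receives a smaller
#' bin.
#'
#' @param x Numeric vector.
#' @param n_bins Number of bins.
#' @return Integer bin labels 1..n_bins (NA preserved).
#' @export
quantile_bins <- function(x, n_bins = 21L) {
  out <- rep(NA_integer_, length(x))
  ok <- which(!is.na(x))
  if (!length(ok)) stop("quantile_bins: all values missing")
  r <- rank(x[ok], ties.method = "first")
  out[ok] <- as.integer(ceiling(r * n_bins / length(ok)))
  out
}

#' Odds ratio of a 2x2 table with optional Haldane-Anscombe correction
#'
#' The sample cross-product ratio `(a*d)/(b*c)`; when any cell is zero, 0.5
#' is added to every cell and the result is flagged with attribute
#' `corrected`.
#'
#' @param a,b,c,d Cell counts (a/b on the focal row, c/d background).
#' @return Numeric odds ratio.
#' @export
odds_ratio <- function(a, b, c, d) {
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  structure((a * d) / (b * c), corrected = corrected)
}

#' Percentile bootstrap confidence interval
#'
#' @param stat_fun Function(index vector) -> scalar statistic, evaluated on
#'   resampled unit indices.
#' @param n_units Number of resampling units.
#' @param n_boot Number of bootstrap replicates.
#' @param level Confidence level.
#' @return Named numeric c(lower, upper).
#' @export
boot_ci <- function(stat_fun, n_units, n_boot = 100L, level = 0.95) {
  reps <- vapply(seq_len(n_boot), function(i) {
    stat_fun(sample.int(n_units, n_units, replace = TRUE))
  }, numeric(1))
  a <- (1 - level) / 2
  stats::quantile(reps, c(a, 1 - a), na.rm = TRUE, names = FALSE) |>
    stats::setNames(c("lower", "upper"))
}

#' Empirical two-sided permutation P value with add-one correction
#' @param observed Observed statistic.
#' @param null Vector of null statistics.
#' @return P value `(b + 1)/(n + 1)` where `b` counts `|null| >= |observed|`.
#' @export
perm_pvalue <- function(observed, null) {
  (sum(abs(null) >= abs(observed)) + 1) / (length(null) + 1)
}

#' Relative difference (a - b)/(a + b)
#' @param a,b Non-negative quantities.
#' @return Relative difference in [-1, 1]; NA when both zero.
#' @export
rel_diff <- function(a, b) {
  out <- (a - b) / (a + b)
  out[(a + b) == 0] <- NA_real_
  out
}
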