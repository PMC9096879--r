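#' Gaussian kernel smoothing with edge renormalization
#'
#' Smooths a series with a discrete Gaussian kernel truncated at +/- 4
#' standard deviations and renormalized wherever the kernel overhangs the
#' series edges, so the output is always a convex combination of the input
#' (values in \[0, 1\] stay in \[0, 1\]). `sd = 0` returns the input
#' unchanged. Smoothing is applied within a series only; callers are
#' responsible for never smoothing across contingency boundaries.
#'
#' @param x Numeric series.
#' @param sd Kernel standard deviation in units of series index.
#' @return Smoothed numeric series of the same length.
#' @export
gaussian_smooth <- function(x, sd = 10) {
  stopifnot(is.numeric(x), sd >= 0)
  n <- length(x)
  if (n == 0L || sd == 0) return(as.numeric(x))
  half <- max(1L, ceiling(4 * sd))
  k <- stats::dnorm(seq(-half, half), sd = sd)
  # pad, convolve, then renormalize by the local kernel mass
  xp <- c(rep(0, half), x, rep(0, half))
  wp <- c(rep(0, half), rep(1, n), rep(0, half))
  num <- stats::filter(xp, k, sides = 2)
  den <- stats::filter(wp, k, sides = 2)
  as.numeric(num[(half + 1):(half + n)] / den[(half + 1):(half + n)])
}

# first index where the series exceeds `threshold`, or n + 1 when it never
# does (the censoring convention used for crossing statistics)
first_crossing <- function(x, threshold = 0.75, censor = TRUE) {
  idx <- which(x > threshold)
  if (length(idx)) idx[1L] else if (censor) length(x) + 1L else NA_integer_
}
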