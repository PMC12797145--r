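#' Shift a series by an integer lag with edge replication
#'
#' Produces the lagged copy of a series used throughout the correction and
#' confound-injection code. A positive lag delays the series (value at time
#' `t` is `x[t - lag]`); the frames that fall outside the observed window are
#' filled by replicating the first (or last) observed value. Using one shift
#' convention everywhere makes noiseless lag/gain recovery exact.
#'
#' @param x Numeric vector.
#' @param lag Integer frame shift; positive delays, negative advances.
#' @return Numeric vector of the same length as `x`.
#' @export
shift_series <- function(x, lag) {
  n <- length(x)
  lag <- as.integer(lag)
  if (abs(lag) >= n) stop("`lag` must be smaller than the series length")
  if (lag == 0L) return(x)
  if (lag > 0L) c(rep(x[1L], lag), x[seq_len(n - lag)])
  else c(x[seq.int(1L - lag, n)], rep(x[n], -lag))
}

#' Fisher z-transform with a degeneracy cap
#'
#' Correlations are capped at `|r| = cap` before `atanh` so that degenerate
#' (perfectly correlated) synthetic cases stay finite.
#'
#' @param r Numeric vector of correlations.
#' @param cap Cap on `|r|` (default 0.999).
#' @return `atanh(pmin(pmax(r, -cap), cap))`.
#' @export
fisher_z <- function(r, cap = 0.999) {
  atanh(pmin(pmax(r, -cap), cap))
}

#' Frequency-domain boxcar bandpass
#'
#' Zeroes every Fourier bin whose frequency lies outside `[low, high]`
#' (inclusive), including the DC bin, and returns the real part of the
#' inverse transform. Applied columnwise when `x` is a matrix. The filter is
#' an exact projection, hence idempotent.
#'
#' @param x Numeric vector or time-by-series matrix.
#' @param dt Sampling interval in seconds.
#' @param low,high Passband edges in Hz.
#' @return Filtered vector/matrix (zero mean by construction).
#' @export
boxcar_bandpass <- function(x, dt, low, high) {
  if (low < 0 || high <= low) stop("need 0 <= low < high")
  vec <- is.null(dim(x))
  xm <- as.matrix(x)
  n <- nrow(xm)
  f <- (seq_len(n) - 1) / (n * dt)
  f <- pmin(f, 1 / dt - f)  # fold to physical frequency
  keep <- f >= low & f <= high
  xf <- mvfft(xm)
  xf[!keep, ] <- 0
  out <- Re(mvfft(xf, inverse = TRUE)) / n
  if (vec) drop(out) else out
}

# Correlation convention used by the density metrics: a constant series
# correlates with nothing (r = 0), so degenerate voxels never poison maps.
# Returns columns scaled so crossprod() gives Pearson correlations.
scale_unit <- function(y) {
  mu <- colMeans(y)
  yc <- sweep(y, 2L, mu)
  ss <- sqrt(colSums(yc^2))
  ss[ss == 0] <- Inf
  sweep(yc, 2L, ss, "/")
}

# Trapezoidal area under (x, y) points.
trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

# Deterministic sub-seed derivation (kept below .Machine$integer.max).
derive_seeds <- function(n) sample.int(.Machine$integer.max - 1L, n)
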