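# Macrovascular correction: extract a prototypical venous reference from the
# maximum-fBV voxel, find each voxel's lag of maximum absolute
# cross-correlation with it, and regress the lag-shifted reference out of
# each voxel as a nuisance regressor. The regressor has the same shape at
# every voxel up to lag and gain — the implemented approximation to a full
# per-voxel vascular simulation.

#' Extract the venous reference signal
#'
#' The series of the voxel with maximum fBV, demeaned and normalized by its
#' maximum absolute value. Ties are broken by the lowest linear voxel index
#' (with a warning).
#'
#' @param v A [volume_series()] with an fBV map.
#' @return Unit-peak, zero-mean numeric series with attribute `voxel` (the
#'   linear index used).
#' @export
extract_venous_reference <- function(v) {
  if (is.null(v$fbv) || all(v$fbv == 0))
    stop("correction error: fBV map is absent or all zero; supply a vessel mask/fBV map")
  mx <- max(v$fbv)
  cand <- which(v$fbv == mx)
  if (length(cand) > 1L)
    warning("multiple voxels share the maximum fBV; using the lowest linear index")
  vox <- min(cand)
  x <- drop(voxel_matrix(v, vox))
  x <- x - mean(x)
  pk <- max(abs(x))
  if (pk == 0) stop("correction error: the maximum-fBV voxel has a constant series")
  ref <- x / pk
  attr(ref, "voxel") <- vox
  ref
}

# Lag search order implementing the tie-break rule: smallest |lag| first,
# negative before positive.
lag_search_order <- function(max_lag) {
  lags <- 0L
  for (l in seq_len(max_lag)) lags <- c(lags, -l, l)
  lags
}

#' Lag of maximum absolute cross-correlation with the reference
#'
#' Searches integer lags in `[-max_lag, max_lag]`, computing the Pearson
#' correlation over the overlapping window at each lag. A positive lag means
#' the voxel lags (follows) the reference. Ties go to the smallest `|lag|`,
#' negative before positive. A constant voxel returns lag 0, correlation 0,
#' flagged via the `degenerate` attribute.
#'
#' @param x Voxel series.
#' @param ref Reference series of the same length.
#' @param max_lag Largest lag searched (default 3; must be `< length / 4`).
#' @return List with `lag` and `xcorr` (maximum absolute correlation).
#' @export
estimate_voxel_lag <- function(x, ref, max_lag = 3L) {
  n <- length(x)
  if (length(ref) != n) stop("series lengths differ")
  if (max_lag >= n / 4) stop("`max_lag` must be smaller than length / 4")
  if (sd(x) == 0) {
    out <- list(lag = 0L, xcorr = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  best <- list(lag = 0L, xcorr = -1)
  for (l in lag_search_order(max_lag)) {
    r <- if (l >= 0L) cor(x[(1L + l):n], ref[seq_len(n - l)])
         else cor(x[seq_len(n + l)], ref[(1L - l):n])
    if (is.na(r)) next
    if (abs(r) > best$xcorr) best <- list(lag = l, xcorr = abs(r))
  }
  best
}

# Vectorized lag estimation for a t x V series matrix; returns integer lags
# and max |r| per column, honouring the same tie-break order.
estimate_lags_matrix <- function(y, ref, max_lag = 3L) {
  n <- nrow(y)
  V <- ncol(y)
  lags <- lag_search_order(max_lag)
  best_r <- rep(-1, V)
  best_l <- integer(V)
  for (l in lags) {
    rs <- if (l >= 0L) suppressWarnings(cor(ref[seq_len(n - l)], y[(1L + l):n, , drop = FALSE]))
          else suppressWarnings(cor(ref[(1L - l):n], y[seq_len(n + l), , drop = FALSE]))
    rs <- abs(as.vector(rs))
    rs[is.na(rs)] <- -2
    take <- rs > best_r
    best_r[take] <- rs[take]
    best_l[take] <- l
  }
  degenerate <- best_r < 0
  best_r[degenerate] <- 0
  best_l[degenerate] <- 0L
  list(lag = best_l, xcorr = best_r, degenerate = degenerate)
}

#' Regress the lag-shifted reference out of every voxel
#'
#' Per voxel, ordinary least squares of the series on an intercept and the
#' reference shifted by that voxel's lag (edge-replicated, see
#' [shift_series()]); the corrected series is the residual plus the voxel
#' mean, so mean-normalized metrics stay defined. Voxels whose shifted
#' regressor is constant are passed through unchanged and flagged.
#'
#' @param v A [volume_series()].
#' @param ref Reference series from [extract_venous_reference()].
#' @param lags Integer array (grid-shaped) or vector over `voxels` of
#'   per-voxel lags.
#' @param voxels Linear indices of voxels to correct (default: union of all
#'   masks, or every voxel when no masks are present).
#' @param xcorr Optional per-voxel maximum absolute cross-correlations to
#'   store in the model.
#' @return List with `volume` (corrected) and `model` (class
#'   `correction_model`: `reference`, per-voxel `lag`, `beta`,
#'   `max_abs_xcorr` arrays).
#' @export
regress_reference <- function(v, ref, lags, voxels = NULL, xcorr = NULL) {
  d <- grid_dim(v)
  if (is.null(voxels)) {
    voxels <- if (length(v$masks)) which(Reduce(`|`, v$masks)) else seq_len(prod(d))
  }
  voxels <- sort(as.integer(voxels))
  lag_vec <- if (length(lags) == prod(d)) as.integer(lags[voxels]) else as.integer(lags)
  if (length(lag_vec) != length(voxels))
    stop("lags were not estimated on the same voxel set")
  y <- voxel_matrix(v, voxels)
  nt <- nrow(y)
  mu <- colMeans(y)
  beta <- rep(NA_real_, length(voxels))
  flagged <- logical(length(voxels))
  for (l in sort(unique(lag_vec))) {
    reg <- shift_series(ref, l)
    sel <- which(lag_vec == l)
    if (sd(reg) == 0) { beta[sel] <- 0; flagged[sel] <- TRUE; next }
    rc <- reg - mean(reg)
    b <- as.vector(crossprod(rc, y[, sel, drop = FALSE])) / sum(rc^2)
    beta[sel] <- b
    y[, sel] <- y[, sel, drop = FALSE] - outer(rc, b)
  }
  y <- sweep(y, 2L, colMeans(y))          # residual of intercept + regressor
  y <- sweep(y, 2L, mu, "+")              # restore the voxel mean
  out <- set_voxel_matrix(v, voxels, y)
  to_array <- function(x) { a <- array(NA_real_, d); a[voxels] <- x; a }
  model <- structure(list(reference = ref,
                          lag = to_array(lag_vec),
                          beta = to_array(beta),
                          max_abs_xcorr = if (is.null(xcorr)) NULL else to_array(xcorr),
                          voxels = voxels,
                          flagged = voxels[flagged]),
                     class = "correction_model")
  list(volume = out, model = model)
}

#' Full macrovascular correction of a volume
#'
#' Extracts the venous reference, estimates each voxel's optimal lag, and
#' regresses the lag-shifted reference out of every in-brain voxel.
#' Correction operates on the raw (unfiltered) series and is intended to run
#' before bandpass preprocessing.
#'
#' @param v A [volume_series()] with an fBV map.
#' @param max_lag Largest lag searched, in frames (default 3, about 13.5 s
#'   at TR 4.5 s).
#' @param voxels Linear indices to correct (default: union of all masks).
#' @return List with `volume` (corrected) and `model` (`correction_model`).
#' @export
correct_volume <- function(v, max_lag = 3L, voxels = NULL) {
  ref <- extract_venous_reference(v)
  d <- grid_dim(v)
  if (is.null(voxels)) {
    voxels <- if (length(v$masks)) which(Reduce(`|`, v$masks)) else seq_len(prod(d))
  }
  voxels <- sort(as.integer(voxels))
  est <- estimate_lags_matrix(voxel_matrix(v, voxels), ref, max_lag)
  regress_reference(v, ref, est$lag, voxels = voxels, xcorr = est$xcorr)
}

#' Re-apply a fitted correction model
#'
#' Applies an existing `correction_model` (same reference, same per-voxel
#' lags) to a volume. Because OLS residuals are exactly orthogonal to their
#' regressors, re-applying a model to its own output is a no-op, which is the
#' sense in which the correction is idempotent.
#'
#' @param v A [volume_series()].
#' @param model A `correction_model` from [regress_reference()].
#' @return List with `volume` and the refitted `model`.
#' @export
apply_correction <- function(v, model) {
  regress_reference(v, model$reference, model$lag, voxels = model$voxels)
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf("<correction_model> %d voxels, lags %d..%d, %d flagged\n",
              length(x$voxels), min(x$lag, na.rm = TRUE),
              max(x$lag, na.rm = TRUE), length(x$flagged)))
  invisible(x)
}
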