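# Seed-independent and seed-based rs-fMRI metrics, computed per voxel on a
# (possibly corrected) volume and reduced to network-wise values.

#' Preprocess a BOLD volume
#'
#' Drops initial frames, regresses the white-matter and CSF mean signals out
#' of every voxel (with intercept), applies a frequency-domain boxcar
#' bandpass, and restores each voxel's pre-filter mean so that
#' mean-normalized metrics (RSFA) remain defined downstream.
#'
#' @param v A [volume_series()] with `white` and `csf` masks.
#' @param band Passband in Hz (default `c(0.01, 0.1)`).
#' @param drop_initial Number of leading frames to discard (default 0; the
#'   synthetic generator does not simulate a steady-state transient).
#' @return A new [volume_series()].
#' @export
preprocess_bold <- function(v, band = c(0.01, 0.1), drop_initial = 0L) {
  nt <- n_frames(v)
  if (nt - drop_initial < 8L) stop("length error: fewer than 8 frames would remain")
  if (is.null(v$masks$white) || !any(v$masks$white) ||
      is.null(v$masks$csf) || !any(v$masks$csf))
    stop("preprocessing error: white-matter and CSF masks must be non-empty")
  if (drop_initial > 0L) {
    v$data <- v$data[, , , -(seq_len(drop_initial)), drop = FALSE]
    nt <- dim(v$data)[4]
  }
  d <- grid_dim(v)
  dat <- matrix(v$data, prod(d), nt)
  wm <- colMeans(dat[which(v$masks$white), , drop = FALSE])
  csf <- colMeans(dat[which(v$masks$csf), , drop = FALSE])
  X <- cbind(1, wm, csf)
  # per-voxel OLS on the two nuisance means; residuals computed in one pass
  beta <- solve(crossprod(X), crossprod(X, t(dat)))
  resid <- t(dat) - X %*% beta
  filtered <- boxcar_bandpass(resid, v$tr, band[1], band[2])
  mu <- rowMeans(dat)
  out <- t(filtered) + mu
  volume_series(array(out, c(d, nt)), tr = v$tr, masks = v$masks, fbv = v$fbv)
}

# Evaluate a per-voxel metric over the gray-matter mask and return a 3D map
# (NA outside gray matter).
map_over_gray <- function(v, fun) {
  gray <- v$masks$gray
  if (is.null(gray) || !any(gray)) stop("gray-matter mask is empty")
  y <- voxel_matrix(v, gray)
  vals <- fun(y)
  out <- array(NA_real_, grid_dim(v))
  out[which(gray)] <- vals
  out
}

#' Resting-state fluctuation amplitude (RSFA)
#'
#' Temporal SD of each gray-matter voxel's series divided by its temporal
#' mean. Voxels with non-positive mean are flagged missing rather than
#' raising an error.
#'
#' @param v A [volume_series()] with a `gray` mask.
#' @return 3D map of RSFA values (NA outside gray matter).
#' @export
compute_rsfa <- function(v) {
  map_over_gray(v, function(y) {
    mu <- colMeans(y)
    s <- apply(y, 2L, sd)
    ifelse(mu > 0, s / mu, NA_real_)
  })
}

#' Global functional connectivity density (gFCD)
#'
#' For each gray-matter voxel, the number of other gray-matter voxels whose
#' Pearson correlation with it reaches the threshold. Constant voxels
#' correlate with nothing.
#'
#' @param v A [volume_series()] with a `gray` mask.
#' @param threshold Correlation threshold in (0, 1) (default 0.6).
#' @return 3D map of counts (NA outside gray matter).
#' @export
compute_gfcd <- function(v, threshold = 0.6) {
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must lie in (0, 1)")
  map_over_gray(v, function(y) {
    z <- scale_unit(y)
    cc <- crossprod(z)
    diag(cc) <- -Inf
    colSums(cc >= threshold)
  })
}

#' Local functional connectivity density (lFCD)
#'
#' Size of the connected cluster grown from each gray-matter voxel by
#' repeatedly adding gray-matter voxels face-adjacent (6-connectivity) to a
#' cluster member that correlate with the index voxel at or above the
#' threshold; the index voxel itself is not counted.
#'
#' @inheritParams compute_gfcd
#' @return 3D map of cluster sizes (NA outside gray matter).
#' @export
compute_lfcd <- function(v, threshold = 0.6) {
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must lie in (0, 1)")
  gray <- v$masks$gray
  if (is.null(gray) || !any(gray)) stop("gray-matter mask is empty")
  idx <- which(gray)
  z <- scale_unit(voxel_matrix(v, gray))
  coords <- which(gray, arr.ind = TRUE)
  counts <- lfcd_cpp(z, coords, dim(gray), threshold)
  out <- array(NA_real_, grid_dim(v))
  out[idx] <- counts
  out
}

#' Sample entropy
#'
#' Negative log conditional probability that sequences matching for `m`
#' points (Chebyshev distance within `r`, self-matches excluded) also match
#' for `m + 1` points. A constant series returns 0 by convention; series with
#' no matches return `NA`.
#'
#' @param x Numeric series.
#' @param m Template length (default 3).
#' @param r_factor Tolerance as a multiple of `sd(x)` (default 0.6).
#' @param r Absolute tolerance; overrides `r_factor` when given.
#' @return Sample entropy value, or `NA` when undefined.
#' @export
sample_entropy <- function(x, m = 3L, r_factor = 0.6, r = NULL) {
  if (length(x) <= m + 1L) return(NA_real_)
  if (is.null(r)) r <- r_factor * sd(x)
  sampen_cpp(as.numeric(x), as.integer(m), r)
}

#' Per-voxel BOLD sample entropy
#'
#' @param v A [volume_series()] with a `gray` mask.
#' @param m Template length (default 3).
#' @param r_factor Tolerance multiplier of each voxel's SD (default 0.6).
#' @return 3D map of sample entropy (NA outside gray matter or undefined).
#' @export
compute_bold_entropy <- function(v, m = 3L, r_factor = 0.6) {
  map_over_gray(v, function(y)
    apply(y, 2L, sample_entropy, m = m, r_factor = r_factor))
}

#' Default network seeds: the in-network voxel nearest each network centroid
#'
#' @param atlas Integer 3D array of network labels (0 = background).
#' @return Named list of linear voxel indices, one per network label.
#' @export
atlas_seeds <- function(atlas) {
  labs <- sort(unique(atlas[atlas > 0]))
  out <- list()
  for (k in labs) {
    co <- which(atlas == k, arr.ind = TRUE)
    cen <- colMeans(co)
    d2 <- rowSums(sweep(co, 2L, cen)^2)
    pick <- co[which.min(d2), , drop = FALSE]
    out[[as.character(k)]] <-
      pick[1] + dim(atlas)[1] * ((pick[2] - 1) + dim(atlas)[2] * (pick[3] - 1))
  }
  out
}

#' Seed-based network functional connectivity
#'
#' Network FC is the mean, over the network's non-seed voxels, of the Fisher
#' z-transformed correlation with the seed-mean series. Correlations are
#' capped at `|r| = 0.999` before the transform; constant voxels contribute
#' `z = 0`.
#'
#' @param v A [volume_series()].
#' @param atlas Integer 3D label array congruent with the grid.
#' @param seeds Named list of seed voxel indices per network (default
#'   [atlas_seeds()]).
#' @return Named numeric vector of per-network FC values.
#' @export
compute_seed_fc <- function(v, atlas, seeds = NULL) {
  if (!identical(dim(atlas), grid_dim(v))) stop("atlas is not congruent with the grid")
  if (is.null(seeds)) seeds <- atlas_seeds(atlas)
  labs <- sort(unique(atlas[atlas > 0]))
  out <- setNames(rep(NA_real_, length(labs)), labs)
  for (k in labs) {
    sk <- seeds[[as.character(k)]]
    if (is.null(sk)) stop("no seed supplied for network ", k)
    seed_series <- rowMeans(voxel_matrix(v, sk))
    vox <- setdiff(which(atlas == k), sk)
    if (!length(vox)) next
    y <- voxel_matrix(v, vox)
    sds <- apply(y, 2L, sd)
    r <- rep(0, ncol(y))
    ok <- sds > 0 & sd(seed_series) > 0
    if (any(ok)) r[ok] <- as.vector(cor(seed_series, y[, ok, drop = FALSE]))
    out[as.character(k)] <- mean(fisher_z(r))
  }
  out
}

#' Reduce a per-voxel metric map to network-wise values
#'
#' Means the map over each network's voxels (missing voxels excluded). With
#' `log_transform`, `log(1 + x)` is applied per voxel before averaging, the
#' zero-tolerant log used for the density metrics.
#'
#' @param map 3D numeric array of per-voxel values.
#' @param atlas Integer 3D label array congruent with the map.
#' @param log_transform Apply `log1p` voxelwise before averaging.
#' @return Named numeric vector of per-network values (NA when a network has
#'   no finite voxels).
#' @export
summarize_network <- function(map, atlas, log_transform = FALSE) {
  if (!identical(dim(map), dim(atlas))) stop("atlas is not congruent with the map")
  labs <- sort(unique(atlas[atlas > 0]))
  vals <- if (log_transform) log1p(map) else map
  out <- setNames(rep(NA_real_, length(labs)), labs)
  for (k in labs) {
    x <- vals[atlas == k]
    x <- x[is.finite(x)]
    if (length(x)) out[as.character(k)] <- mean(x)
  }
  out
}

#' Compute the network-wise fMRI metric table for one participant
#'
#' Runs the five rs-fMRI metrics (RSFA, seed-based FC, gFCD, lFCD, BOLD
#' sample entropy) on a preprocessed volume and reduces them to network
#' values; the density metrics are `log1p`-transformed voxelwise before
#' averaging.
#'
#' @param v A (preprocessed, possibly corrected) [volume_series()].
#' @param atlas Integer 3D label array.
#' @param participant Participant identifier for the output rows.
#' @param state Correction state label (`"pre"` or `"post"`).
#' @param metrics Subset of [fmri_metric_names()] to compute.
#' @param fcd_threshold Correlation threshold for the density metrics
#'   (default 0.6).
#' @param entropy_m,entropy_r Sample-entropy parameters (defaults 3, 0.6).
#' @param seeds Seed list for [compute_seed_fc()].
#' @return A metric table (see [metric_table()]).
#' @export
compute_fmri_metrics <- function(v, atlas, participant, state = "pre",
                                 metrics = fmri_metric_names(),
                                 fcd_threshold = 0.6,
                                 entropy_m = 3L, entropy_r = 0.6,
                                 seeds = NULL) {
  rows <- list()
  add <- function(metric, values)
    metric_table(participant, as.integer(names(values)), metric, "fmri",
                 state, values)
  if ("rsfa" %in% metrics)
    rows$rsfa <- add("rsfa", summarize_network(compute_rsfa(v), atlas))
  if ("fc" %in% metrics)
    rows$fc <- add("fc", compute_seed_fc(v, atlas, seeds))
  if ("gfcd" %in% metrics)
    rows$gfcd <- add("gfcd", summarize_network(compute_gfcd(v, fcd_threshold),
                                               atlas, log_transform = TRUE))
  if ("lfcd" %in% metrics)
    rows$lfcd <- add("lfcd", summarize_network(compute_lfcd(v, fcd_threshold),
                                               atlas, log_transform = TRUE))
  if ("entropy" %in% metrics)
    rows$entropy <- add("entropy",
                        summarize_network(compute_bold_entropy(v, entropy_m,
                                                               entropy_r), atlas))
  do.call(rbind, unname(rows))
}
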