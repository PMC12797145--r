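# Synthetic geometry: a small 3D grid with compact cubic network blobs at
# octant centres, white-matter and CSF blocks in the spare octant, and a
# straight vessel line through the middle of the grid. Spatial units are
# voxels; no anatomical registration is implied.

blob_bounds <- function(center, side, dmax) {
  lo <- max(1L, center - (side %/% 2L) + 1L)
  hi <- min(dmax, lo + side - 1L)
  lo:hi
}

#' Build the synthetic network atlas and tissue masks
#'
#' Places `n_networks` compact cubic blobs (labels 1..n) at octant centres of
#' the grid; the spare octant hosts white-matter and CSF blocks used by the
#' nuisance-regression step. Gray matter is the union of the network blobs.
#'
#' @param config A [sim_config()].
#' @return List with `atlas` (integer 3D array, 0 = background), and logical
#'   masks `gray`, `white`, `csf`.
#' @export
make_atlas <- function(config) {
  d <- config$grid_dim
  side <- max(2L, round(config$voxels_per_network^(1 / 3)))
  q1 <- pmax(2L, round(d * 0.25))
  q3 <- pmin(d - 1L, round(d * 0.75))
  centers <- as.matrix(expand.grid(x = c(q1[1], q3[1]),
                                   y = c(q1[2], q3[2]),
                                   z = c(q1[3], q3[3])))
  if (config$n_networks > 7L)
    stop("configuration error: at most 7 networks fit the octant layout")
  atlas <- array(0L, d)
  for (n in seq_len(config$n_networks)) {
    cx <- centers[n, ]
    atlas[blob_bounds(cx[1], side, d[1]),
          blob_bounds(cx[2], side, d[2]),
          blob_bounds(cx[3], side, d[3])] <- n
  }
  spare <- centers[8L, ]
  white <- array(FALSE, d)
  white[blob_bounds(spare[1] - 1L, side, d[1]),
        blob_bounds(spare[2] - 1L, side, d[2]),
        blob_bounds(spare[3] - 1L, side, d[3])] <- TRUE
  csf <- array(FALSE, d)
  csf[blob_bounds(min(spare[1] + 2L, d[1] - 1L), 3L, d[1]),
      blob_bounds(min(spare[2] + 2L, d[2] - 1L), 3L, d[2]),
      blob_bounds(min(spare[3] + 2L, d[3] - 1L), 3L, d[3])] <- TRUE
  white <- white & atlas == 0L & !csf
  csf <- csf & atlas == 0L
  list(atlas = atlas, gray = atlas > 0L, white = white, csf = csf)
}

#' Build the synthetic vessel model
#'
#' A straight vessel line along z through the grid centre. The fBV map decays
#' exponentially with the distance to the vessel and is exactly zero beyond a
#' fixed dilation radius; along the vessel itself the fBV peaks at a single
#' mid-line voxel (mimicking a caliber maximum) so the venous-reference
#' extraction has a unique argmax.
#'
#' @param config A [sim_config()].
#' @param fbv_decay Decay length (voxels) of the fBV falloff (default 1.5).
#' @param dilation_radius Distance beyond which fBV is exactly 0 (default 6).
#' @return List with `mask` (logical 3D), `fbv` (3D in `[0, 1]`), and `dist`
#'   (3D Euclidean distance to the vessel, in voxels).
#' @export
make_vessel <- function(config, fbv_decay = 1.5, dilation_radius = 6) {
  d <- config$grid_dim
  cx <- d[1] %/% 2L
  cy <- d[2] %/% 2L
  mask <- array(FALSE, d)
  mask[cx, cy, ] <- TRUE
  ix <- slice.index(mask, 1L)
  iy <- slice.index(mask, 2L)
  dist <- sqrt((ix - cx)^2 + (iy - cy)^2)  # line spans all z: xy distance
  fbv <- exp(-dist / fbv_decay)
  fbv[dist > dilation_radius] <- 0
  z0 <- d[3] %/% 2L
  iz <- slice.index(mask, 3L)
  profile <- 0.9 + 0.1 * exp(-((iz - z0)^2) / 8)
  fbv[mask] <- profile[mask]
  list(mask = mask, fbv = fbv, dist = dist)
}
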