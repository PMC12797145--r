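# Fixture builders shared across the test files. All fixtures are generated
# in code under fixed seeds.

# Reduced-size configuration for fast volumetric tests; the full-size study
# conditions (sim_config() defaults) are exercised by the acceptance tests.
small_cfg <- function(n_participants = 3L, eeg_duration_s = 120,
                      n_volumes = 26L, sources_per_network = 2L,
                      master_seed = 11L, ...) {
  sim_config(n_participants = n_participants, eeg_duration_s = eeg_duration_s,
             n_volumes = n_volumes, sources_per_network = sources_per_network,
             master_seed = master_seed, ...)
}

# Wrap a t x V series matrix into a volume_series laid out along a given 3D
# grid (voxels fill the grid in linear order); all voxels are gray matter.
vol_from_matrix <- function(y, dims = c(ncol(y), 1L, 1L), tr = 1,
                            masks = NULL, fbv = NULL) {
  stopifnot(prod(dims) == ncol(y))
  dat <- array(t(y), c(dims, nrow(y)))  # voxel-major fill per frame
  if (is.null(masks)) masks <- list(gray = array(TRUE, dims))
  volume_series(dat, tr = tr, masks = masks, fbv = fbv)
}

# Component of b orthogonal to a and to the intercept, unit SD.
orthogonalize <- function(b, a) {
  r <- unname(residuals(lm(b ~ a)))
  r / sd(r)
}

# A source_signals object holding the given rows at the given rate.
src_set <- function(rows, rate = 125, network = NULL) {
  m <- do.call(rbind, rows)
  if (is.null(network)) network <- rep(1L, nrow(m))
  source_signals(m, rate = rate, network = network)
}
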