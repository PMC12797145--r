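#' Construct a 4D BOLD-like volume series
#'
#' Container for a voxel-by-time dataset with its repetition interval,
#' tissue/vessel masks and macrovascular blood-volume-fraction (fBV) map.
#'
#' @param data 4D numeric array (x, y, z, t) with at least 2 frames.
#' @param tr Repetition interval in seconds.
#' @param masks Named list of logical 3D arrays congruent with the grid;
#'   conventional names are `gray`, `white`, `csf`, `vessel`.
#' @param fbv Optional 3D array of per-voxel blood-volume fractions in
#'   `[0, 1]`.
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, tr, masks = list(), fbv = NULL) {
  if (length(dim(data)) != 4L) stop("`data` must be a 4D array (x, y, z, t)")
  if (dim(data)[4] < 2L) stop("`data` must have at least 2 frames")
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("`tr` must be a positive duration in seconds")
  if (any(!is.finite(data))) stop("`data` contains non-finite values")
  gd <- dim(data)[1:3]
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!identical(dim(m), gd)) stop("mask '", nm, "' is not congruent with the grid")
    masks[[nm]] <- array(as.logical(m), gd)
  }
  if (!is.null(fbv)) {
    if (!identical(dim(fbv), gd)) stop("`fbv` is not congruent with the grid")
    if (any(fbv < 0 | fbv > 1, na.rm = TRUE)) stop("`fbv` must lie in [0, 1]")
  }
  structure(list(data = data, tr = tr, masks = masks, fbv = fbv),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_series> %d x %d x %d grid, %d frames, TR %.3g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  if (length(x$masks)) cat("  masks:", paste(names(x$masks), collapse = ", "), "\n")
  if (!is.null(x$fbv)) cat(sprintf("  fBV: max %.3g\n", max(x$fbv)))
  invisible(x)
}

n_frames <- function(v) dim(v$data)[4]
grid_dim <- function(v) dim(v$data)[1:3]

# t x V matrix of the series of the voxels selected by a logical mask (or
# linear indices), in increasing linear-index order.
voxel_matrix <- function(v, voxels) {
  d <- dim(v$data)
  idx <- if (is.logical(voxels)) which(voxels) else sort(as.integer(voxels))
  nvox <- prod(d[1:3])
  m <- matrix(v$data, nrow = nvox, ncol = d[4])
  t(m[idx, , drop = FALSE])
}

# Write a t x V matrix back into the 4D array at the given linear indices.
set_voxel_matrix <- function(v, voxels, series) {
  d <- dim(v$data)
  idx <- if (is.logical(voxels)) which(voxels) else sort(as.integer(voxels))
  nvox <- prod(d[1:3])
  m <- matrix(v$data, nrow = nvox, ncol = d[4])
  m[idx, ] <- t(series)
  v$data <- array(m, d)
  v
}

#' Construct an EEG-like source signal set
#'
#' @param data Sources-by-samples numeric matrix.
#' @param rate Sampling frequency in Hz; must exceed 100 Hz so the 30-50 Hz
#'   band is resolvable.
#' @param network Integer network id per source.
#' @return An object of class `source_signals`.
#' @export
source_signals <- function(data, rate, network) {
  data <- as.matrix(data)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 100)
    stop("`rate` must exceed 100 Hz (the 30-50 Hz band must be resolvable)")
  rate <- as.numeric(rate)
  if (length(network) != nrow(data))
    stop("`network` must give one network id per source")
  if (any(!is.finite(data))) stop("`data` contains non-finite values")
  structure(list(data = data, rate = rate, network = as.integer(network)),
            class = "source_signals")
}

#' @export
print.source_signals <- function(x, ...) {
  cat(sprintf("<source_signals> %d sources x %d samples at %g Hz (%d networks)\n",
              nrow(x$data), ncol(x$data), x$rate, length(unique(x$network))))
  invisible(x)
}

#' Assemble metric-table rows
#'
#' Long-format records of network-wise metric values: one row per
#' (participant, network, metric, correction state).
#'
#' @param participant Participant identifier (recycled).
#' @param network Integer network ids.
#' @param metric Metric name (recycled).
#' @param modality `"fmri"` or `"eeg"` (recycled).
#' @param state Correction state, `"pre"`, `"post"`, or `NA` for
#'   state-independent (EEG) metrics.
#' @param value Numeric metric values (non-finite values are stored as `NA`).
#' @return A `data.frame` with the metric-table columns.
#' @export
metric_table <- function(participant, network, metric, modality, state, value) {
  value[!is.finite(value)] <- NA_real_
  data.frame(participant = participant, network = as.integer(network),
             metric = metric, modality = modality, state = state,
             value = as.numeric(value), stringsAsFactors = FALSE)
}
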