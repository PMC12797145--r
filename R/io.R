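# Formats: NIfTI volumes (RNifti), delimited EEG matrices with JSON
# sidecars, TSV metric tables, JSON configs. All writers are deterministic
# given identical inputs.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a volume series to NIfTI
#'
#' Stores the 4D data (float32) with the TR in `pixdim[4]`; masks and the
#' fBV map are written as companion 3D files next to the main volume
#' (`<stem>_mask_<name>.nii.gz`, `<stem>_fbv.nii.gz`).
#'
#' @param v A [volume_series()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @param companions Write mask/fBV companion files (default TRUE).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, companions = TRUE) {
  img <- RNifti::asNifti(v$data, list(pixdim = c(-1, 1, 1, 1, v$tr, 0, 0, 0)),
                         datatype = "float")
  RNifti::writeNifti(img, path)
  if (companions) {
    stem <- sub("\\.nii(\\.gz)?$", "", path)
    for (nm in names(v$masks))
      RNifti::writeNifti(RNifti::asNifti(array(as.integer(v$masks[[nm]]),
                                               dim(v$masks[[nm]])),
                                         datatype = "uint8"),
                         paste0(stem, "_mask_", nm, ".nii.gz"))
    if (!is.null(v$fbv))
      RNifti::writeNifti(RNifti::asNifti(v$fbv, datatype = "float"),
                         paste0(stem, "_fbv.nii.gz"))
  }
  invisible(path)
}

#' Read a volume series from NIfTI
#'
#' @param path 4D NIfTI file.
#' @param tr Repetition interval override; by default taken from
#'   `pixdim[4]`, and required explicitly when the header carries none.
#' @param companions Also look for the mask/fBV companion files written by
#'   [write_volume()] (default TRUE).
#' @return A [volume_series()].
#' @export
read_volume <- function(path, tr = NULL, companions = TRUE) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L)
    stop("shape error: expected a 4D BOLD volume, got ", length(dim(img)), "D")
  if (is.null(tr)) {
    pd <- RNifti::pixdim(img)
    if (length(pd) < 4L || !is.finite(pd[4]) || pd[4] <= 0)
      stop("no TR in the header; pass `tr` explicitly")
    tr <- pd[4]
  }
  dat <- array(as.numeric(img), dim(img))
  if (any(!is.finite(dat))) {
    bad <- which(!is.finite(dat))[1]
    stop("non-finite voxel values (first at linear index ", bad, ")")
  }
  masks <- list()
  fbv <- NULL
  if (companions) {
    stem <- sub("\\.nii(\\.gz)?$", "", path)
    for (f in Sys.glob(paste0(stem, "_mask_*.nii.gz"))) {
      nm <- sub(".*_mask_(.*)\\.nii\\.gz$", "\\1", f)
      m <- RNifti::readNifti(f)
      masks[[nm]] <- array(as.numeric(m) > 0.5, dim(m))
    }
    fpath <- paste0(stem, "_fbv.nii.gz")
    if (file.exists(fpath)) {
      fi <- RNifti::readNifti(fpath)
      fbv <- array(as.numeric(fi), dim(fi))
    }
  }
  volume_series(dat, tr = tr, masks = masks, fbv = fbv)
}

#' Write an atlas (or any 3D label array) to NIfTI
#'
#' @param atlas Integer 3D array.
#' @param path Output path (labels stored as uint16).
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(atlas), dim(atlas)),
                                     datatype = "uint16"), path)
  invisible(path)
}

#' Read a 3D label atlas from NIfTI
#'
#' @param path NIfTI file with integer labels.
#' @return Integer 3D array.
#' @export
read_atlas <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("shape error: expected a 3D atlas")
  array(as.integer(img), dim(img))
}

#' Write EEG source signals as a delimited matrix plus JSON sidecar
#'
#' The matrix is sources-by-samples, tab-delimited without headers; the
#' sidecar records `rate_hz` and `source_network_id`.
#'
#' @param s A [source_signals()] object.
#' @param path Output `.tsv` path; the sidecar replaces the extension with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(s, path) {
  write.table(s$data, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  sidecar <- sub("\\.[^.]+$", ".json", path)
  jsonlite::write_json(list(rate_hz = s$rate, source_network_id = s$network),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read EEG source signals from a delimited matrix plus JSON sidecar
#'
#' @param path Delimited sources-by-samples matrix (no header).
#' @param sidecar JSON sidecar path (default: `path` with `.json`
#'   extension); must contain `rate_hz` and `source_network_id`.
#' @return A [source_signals()] object.
#' @export
read_eeg <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sub("\\.[^.]+$", ".json", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$rate_hz))
    stop("sidecar `", sidecar, "` is missing the required key `rate_hz`")
  if (is.null(meta$source_network_id))
    stop("sidecar `", sidecar, "` is missing the required key `source_network_id`")
  dat <- tryCatch(as.matrix(read.table(path, sep = "\t", header = FALSE)),
                  error = function(e)
                    stop("parse error reading `", path, "`: ", conditionMessage(e)))
  if (!is.numeric(dat)) stop("parse error: non-numeric entries in `", path, "`")
  source_signals(dat, rate = meta$rate_hz, network = meta$source_network_id)
}

#' Write a metric table as TSV
#'
#' @param table A metric table (see [metric_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(table, path) write_tsv(table, path)

#' Read a metric table from TSV
#'
#' @param path TSV written by [write_metric_table()].
#' @return A metric-table `data.frame`.
#' @export
read_metric_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a synthetic cohort to a directory
#'
#' Per-participant 4D BOLD (with mask/fBV companions) and EEG matrix +
#' sidecar, the shared atlas, the ground truth and the resolved
#' configuration as JSON.
#'
#' @param cohort A cohort from [make_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_atlas(cohort$atlas, file.path(dir, "atlas.nii.gz"))
  for (i in seq_along(cohort$participants)) {
    p <- cohort$participants[[i]]
    write_volume(p$bold, file.path(dir, sprintf("sub-%02d_bold.nii.gz", i)),
                 companions = i == 1L)
    if (!is.null(p$eeg))
      write_eeg(p$eeg, file.path(dir, sprintf("sub-%02d_eeg.tsv", i)))
  }
  truth <- cohort$truth
  truth$references <- NULL
  truth$confound_field <- NULL
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(cohort$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A cohort list compatible with the analysis functions.
#' @export
read_cohort <- function(dir) {
  cfgl <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- do.call(sim_config, cfgl[setdiff(names(cfgl), character(0))])
  atlas <- read_atlas(file.path(dir, "atlas.nii.gz"))
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  bolds <- sort(Sys.glob(file.path(dir, "sub-*_bold.nii.gz")))
  shared <- read_volume(bolds[1], companions = TRUE)
  participants <- lapply(seq_along(bolds), function(i) {
    v <- if (i == 1L) shared else read_volume(bolds[i], companions = FALSE)
    v$masks <- shared$masks
    v$fbv <- shared$fbv
    epath <- file.path(dir, sprintf("sub-%02d_eeg.tsv", i))
    eeg <- if (file.exists(epath)) read_eeg(epath) else NULL
    list(bold = v, eeg = eeg)
  })
  list(participants = participants, atlas = atlas,
       truth = truth, config = config)
}
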