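# End-to-end pipeline: preprocess -> metrics (pre) -> macrovascular
# correction -> metrics (post) -> association grid -> LME + FDR -> paired
# r-squared comparison -> polarity matrix.

#' Compute both correction states' fMRI metric tables for a cohort
#'
#' For each participant: the "pre" state preprocesses the volume as acquired
#' (confound included when injected); the "post" state applies the
#' macrovascular correction first, then the same preprocessing.
#'
#' @param cohort A cohort from [make_cohort()] or [read_cohort()].
#' @param metrics fMRI metrics to compute (default all five).
#' @param band Bandpass passband (default `c(0.01, 0.1)` Hz).
#' @param drop_initial Leading frames to drop (default 0).
#' @param max_lag Correction lag search bound (default 3 frames).
#' @param states Which states to compute (default both).
#' @return A metric table covering all participants, networks and states.
#' @export
cohort_fmri_metrics <- function(cohort, metrics = fmri_metric_names(),
                                band = c(0.01, 0.1), drop_initial = 0L,
                                max_lag = 3L, states = c("pre", "post")) {
  atlas <- cohort$atlas
  seeds <- atlas_seeds(atlas)
  out <- list()
  for (i in seq_along(cohort$participants)) {
    v <- cohort$participants[[i]]$bold
    if ("pre" %in% states) {
      vp <- preprocess_bold(v, band = band, drop_initial = drop_initial)
      out[[length(out) + 1L]] <-
        compute_fmri_metrics(vp, atlas, i, "pre", metrics, seeds = seeds)
    }
    if ("post" %in% states) {
      vc <- correct_volume(v, max_lag = max_lag)$volume
      vc <- preprocess_bold(vc, band = band, drop_initial = drop_initial)
      out[[length(out) + 1L]] <-
        compute_fmri_metrics(vc, atlas, i, "post", metrics, seeds = seeds)
    }
  }
  do.call(rbind, out)
}

#' Compute the EEG metric table for a cohort
#'
#' @param cohort A cohort from [make_cohort()] or [read_cohort()].
#' @param metrics EEG metrics to compute (default all thirteen).
#' @return A metric table covering all participants and networks.
#' @export
cohort_eeg_metrics <- function(cohort, metrics = eeg_metric_names()) {
  out <- lapply(seq_along(cohort$participants), function(i) {
    s <- cohort$participants[[i]]$eeg
    if (is.null(s)) stop("cohort was generated without EEG signals")
    compute_eeg_metrics(s, i, metrics)
  })
  do.call(rbind, out)
}

#' Run the full association analysis on a cohort
#'
#' Executes the whole pipeline on a synthetic (or loaded) cohort and,
#' optionally, writes the association table, the paired r-squared
#' comparison, the polarity matrix and the resolved configuration beside
#' each other in `out_dir`.
#'
#' @param cohort A cohort from [make_cohort()] or [read_cohort()].
#' @param out_dir Optional output directory for the TSV/JSON artifacts.
#' @param q FDR level (default 0.05).
#' @param random Random-effect structure (see [fit_lme()]).
#' @param metrics_fmri,metrics_eeg Metric subsets (defaults: all).
#' @param band,drop_initial,max_lag Pipeline parameters (see
#'   [cohort_fmri_metrics()]).
#' @return List with `associations`, `r2_comparison` (paired Wilcoxon,
#'   pre vs post families matched on Y and X), `polarity` (post-state signed
#'   matrix), and the two metric tables.
#' @export
run_full_analysis <- function(cohort, out_dir = NULL, q = 0.05,
                              random = "participant",
                              metrics_fmri = fmri_metric_names(),
                              metrics_eeg = eeg_metric_names(),
                              band = c(0.01, 0.1), drop_initial = 0L,
                              max_lag = 3L) {
  fmri <- cohort_fmri_metrics(cohort, metrics = metrics_fmri, band = band,
                              drop_initial = drop_initial, max_lag = max_lag)
  eeg <- cohort_eeg_metrics(cohort, metrics = metrics_eeg)
  sex <- data.frame(participant = seq_along(cohort$participants),
                    sex = cohort$truth$sex)
  grid <- build_grid(fmri, eeg, sex)
  assoc <- run_associations(grid, q = q, random = random)

  pre <- assoc[assoc$state == "pre", c("y", "x", "r2_adj")]
  post <- assoc[assoc$state == "post", c("y", "x", "r2_adj")]
  m <- merge(pre, post, by = c("y", "x"), suffixes = c("_pre", "_post"))
  r2cmp <- if (nrow(m) >= 6L) compare_r2(m$r2_adj_pre, m$r2_adj_post)
  else list(statistic = NA_real_, p_value = NA_real_, n_effective = nrow(m),
            median_difference = median(m$r2_adj_post - m$r2_adj_pre),
            degenerate = TRUE)
  pol <- polarity_matrix(assoc, state = "post")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metric_table(fmri, file.path(out_dir, "fmri_metrics.tsv"))
    write_metric_table(eeg, file.path(out_dir, "eeg_metrics.tsv"))
    write_tsv(assoc, file.path(out_dir, "associations.tsv"))
    write_tsv(cbind(m, data.frame(wilcoxon_p = r2cmp$p_value)),
              file.path(out_dir, "r2_comparison.tsv"))
    write_tsv(data.frame(y = rownames(pol), pol, check.names = FALSE),
              file.path(out_dir, "polarity_matrix.tsv"))
    jsonlite::write_json(
      list(q = q, random = random, band = band, drop_initial = drop_initial,
           max_lag = max_lag, config = unclass(cohort$config)),
      file.path(out_dir, "run_config.json"), auto_unbox = TRUE, digits = NA)
  }
  list(associations = assoc, r2_comparison = r2cmp, polarity = pol,
       fmri_table = fmri, eeg_table = eeg)
}
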