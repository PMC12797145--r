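#' Canonical EEG frequency bands
#'
#' Delta 1-4, theta 4-8, alpha 8-12, beta 12-30 and low gamma 30-50 Hz.
#' Bins are assigned to bands by half-open intervals `[low, high)` except
#' gamma, which closes at 50 Hz, so shared edges are never double-counted.
#'
#' @return A `data.frame` with columns `band`, `low`, `high`.
#' @export
band_scheme <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "gamma"),
             low  = c(1, 4, 8, 12, 30),
             high = c(4, 8, 12, 30, 50),
             stringsAsFactors = FALSE)
}

#' Metric name vocabularies
#'
#' The fMRI metric set and the EEG metric set crossed by the association
#' grid: 5 fMRI metrics by 13 EEG metrics (5 band coherences, broadband
#' coherence, 5 band fractional powers, normalized total power, and the
#' multiscale-entropy complexity index).
#'
#' @return Character vector of metric names.
#' @export
fmri_metric_names <- function() c("rsfa", "fc", "gfcd", "lfcd", "entropy")

#' @rdname fmri_metric_names
#' @export
eeg_metric_names <- function() {
  b <- band_scheme()$band
  c(paste0("coh_", b), "coh_broadband", paste0("power_", b), "power_total", "ci")
}

#' Simulation configuration for the synthetic cohort generator
#'
#' Defaults reproduce the emulated study conditions: 20 participants
#' (balanced sex), 7 functional networks, BOLD at TR 4.5 s over a 4-minute
#' run (53 frames), EEG source signals at 125 Hz for 240 s. The remaining
#' parameters are the generator's own calibration; see the methods vignette
#' for the rationale behind each default.
#'
#' @param n_participants Number of participants (default 20).
#' @param n_networks Number of functional networks (default 7).
#' @param voxels_per_network Voxels per network blob (default 64, a 4^3 cube).
#' @param grid_dim 3D grid extent in voxels (default `c(16, 16, 16)`).
#' @param tr_seconds BOLD repetition interval (default 4.5 s).
#' @param n_volumes BOLD frames retained (default `floor(240 / 4.5)` = 53).
#' @param eeg_rate_hz EEG sampling rate (default 125 Hz).
#' @param eeg_duration_s EEG record length (default 240 s).
#' @param sources_per_network EEG sources per network (default 2).
#' @param coupling_beta Ground-truth slope linking the participant-level EEG
#'   latent to BOLD network amplitude (default 0.5).
#' @param sex_interaction Multiplicative modulation of `coupling_beta` by
#'   sex (default 0.3).
#' @param sex_main Sex main effect on BOLD network amplitude, log scale
#'   (default 0.1).
#' @param confound_amplitude Venous signal gain at the vessel, in units of
#'   the voxel noise SD (default 3; 0 disables injection).
#' @param confound_decay Length scale (voxels) of the perivascular
#'   contamination decay (default 2.5).
#' @param confound_gain_sd SD of the per-participant lognormal venous gain
#'   (default 0.4).
#' @param max_confound_lag Largest injected venous lag in frames (default 3).
#' @param noise_sd Voxelwise BOLD noise SD (default 1).
#' @param bold_signal_amp Network signal amplitude at latent 0 (default 1).
#' @param baseline BOLD baseline intensity (default 100).
#' @param network_jitter SD of the per-network jitter added to the
#'   participant latent (default 0.3).
#' @param master_seed Integer seed; identical seeds give bit-identical
#'   cohorts.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 20L, n_networks = 7L,
                       voxels_per_network = 64L, grid_dim = c(16L, 16L, 16L),
                       tr_seconds = 4.5, n_volumes = 53L,
                       eeg_rate_hz = 125, eeg_duration_s = 240,
                       sources_per_network = 2L,
                       coupling_beta = 0.5, sex_interaction = 0.3,
                       sex_main = 0.1,
                       confound_amplitude = 3, confound_decay = 2.5,
                       confound_gain_sd = 0.4, max_confound_lag = 3L,
                       noise_sd = 1, bold_signal_amp = 1, baseline = 100,
                       network_jitter = 0.3, master_seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              n_networks = as.integer(n_networks),
              voxels_per_network = as.integer(voxels_per_network),
              grid_dim = as.integer(grid_dim),
              tr_seconds = tr_seconds, n_volumes = as.integer(n_volumes),
              eeg_rate_hz = eeg_rate_hz, eeg_duration_s = eeg_duration_s,
              sources_per_network = as.integer(sources_per_network),
              coupling_beta = coupling_beta, sex_interaction = sex_interaction,
              sex_main = sex_main,
              confound_amplitude = confound_amplitude,
              confound_decay = confound_decay,
              confound_gain_sd = confound_gain_sd,
              max_confound_lag = as.integer(max_confound_lag),
              noise_sd = noise_sd, bold_signal_amp = bold_signal_amp,
              baseline = baseline, network_jitter = network_jitter,
              master_seed = as.integer(master_seed))
  counts <- c("n_participants", "n_networks", "voxels_per_network",
              "n_volumes", "sources_per_network")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop("configuration error: `", nm, "` must be a count >= 1")
  }
  if (length(cfg$grid_dim) != 3L || any(cfg$grid_dim < 8L))
    stop("configuration error: `grid_dim` must be three extents >= 8")
  if (cfg$tr_seconds <= 0 || cfg$eeg_duration_s <= 0)
    stop("configuration error: durations must be positive")
  if (cfg$eeg_rate_hz <= 2 * 50)
    stop("configuration error: `eeg_rate_hz` must exceed twice the highest band edge (50 Hz)")
  if (cfg$confound_amplitude < 0)
    stop("configuration error: `confound_amplitude` must be >= 0")
  if (cfg$max_confound_lag < 0 || cfg$max_confound_lag >= cfg$n_volumes)
    stop("configuration error: `max_confound_lag` must lie in [0, n_volumes)")
  if (cfg$n_volumes * cfg$tr_seconds > cfg$eeg_duration_s + 1e-9)
    stop("configuration error: drivers must cover the scan duration")
  class(cfg) <- "sim_config"
  cfg
}

# Driver band-power mixture at latent 0: alpha-dominant spectrum plus a
# broadband floor. The participant latent multiplies the alpha weight on the
# log scale before renormalization (see make_neuronal_drivers).
driver_band_weights <- function() {
  c(delta = 0.10, theta = 0.10, alpha = 0.50, beta = 0.20, gamma = 0.10)
}
driver_broadband_floor <- function() 0.10
driver_latent_gain <- function() 0.5
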