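# Synthetic cohort generator. The generative model (documented in the
# methods vignette): each network has one band-limited Gaussian driver whose
# band-power mixture is alpha-dominant; a participant-by-network latent
# variable shifts the alpha weight (EEG side) and, scaled by the ground-truth
# coupling slope, the BOLD network amplitude (fMRI side). BOLD voxels carry
# the hemodynamically low-passed driver envelope plus white noise; a lagged,
# spatially decaying venous confound can be injected around the vessel.

#' Generate per-network neuronal driver signals
#'
#' Each driver is a unit-variance Gaussian process whose power spectrum is a
#' mixture of the five canonical bands plus a flat 1-50 Hz broadband floor.
#' The network latent multiplies the alpha band weight on the log scale
#' before renormalization, so larger latents yield larger alpha fractional
#' power while total power stays fixed.
#'
#' @param config A [sim_config()].
#' @param participant_seed Integer seed; identical seeds give identical
#'   drivers.
#' @param latents Numeric vector of per-network latents (default all 0).
#' @return Matrix of `n_networks` rows by `eeg_rate_hz * eeg_duration_s`
#'   columns.
#' @export
make_neuronal_drivers <- function(config, participant_seed, latents = NULL) {
  if (config$eeg_rate_hz <= 2 * 50)
    stop("configuration error: sampling rate too low for the 30-50 Hz band")
  K <- config$n_networks
  if (is.null(latents)) latents <- rep(0, K)
  if (length(latents) != K) stop("`latents` must have one value per network")
  set.seed(as.integer(participant_seed))
  n <- round(config$eeg_rate_hz * config$eeg_duration_s)
  f <- (seq_len(n) - 1) * config$eeg_rate_hz / n
  f <- pmin(f, config$eeg_rate_hz - f)
  bands <- band_scheme()
  in_band <- lapply(seq_len(nrow(bands)), function(b) {
    if (bands$band[b] == "gamma") f >= bands$low[b] & f <= bands$high[b]
    else f >= bands$low[b] & f < bands$high[b]
  })
  broad <- f >= 1 & f <= 50
  out <- matrix(0, K, n)
  for (k in seq_len(K)) {
    w <- driver_band_weights()
    w["alpha"] <- w["alpha"] * exp(driver_latent_gain() * latents[k])
    w <- w / sum(w) * (1 - driver_broadband_floor())
    S <- numeric(n)
    for (b in seq_along(in_band)) S[in_band[[b]]] <- S[in_band[[b]]] + w[b] / sum(in_band[[b]])
    S[broad] <- S[broad] + driver_broadband_floor() / sum(broad)
    z <- fft(rnorm(n)) * sqrt(S)
    y <- Re(fft(z, inverse = TRUE)) / n
    out[k, ] <- (y - mean(y)) / sd(y)
  }
  out
}

# Canonical double-gamma hemodynamic kernel (peak 6 s, undershoot 16 s),
# sampled at interval dt and normalized to unit sum.
hrf_kernel <- function(dt, length_s = 32) {
  t <- seq(0, length_s, by = dt)
  h <- t^5 * exp(-t) / gamma(6) - t^15 * exp(-t) / gamma(16) / 6
  h / sum(h)
}

# Slow hemodynamic expression of a driver: rectified envelope, low-passed,
# convolved with the canonical kernel, sampled at the TR grid, unit SD.
driver_to_bold <- function(driver, config) {
  dt <- 1 / config$eeg_rate_hz
  env <- boxcar_bandpass(abs(driver), dt, 0, 0.2)
  h <- hrf_kernel(dt)
  conv <- stats::convolve(env, rev(h), type = "open")[seq_along(env)]
  idx <- round(seq(0, config$n_volumes - 1) * config$tr_seconds / dt) + 1
  y <- conv[idx]
  s <- sd(y)
  if (s == 0) rep(0, length(y)) else (y - mean(y)) / s
}

# Venous reference waveform on the TR grid: low-frequency (< 0.1 Hz)
# filtered noise plus an (aliased) respiratory-band sinusoid, unit SD.
make_venous_waveform <- function(config) {
  nv <- config$n_volumes
  t_sec <- seq(0, nv - 1) * config$tr_seconds
  slow <- boxcar_bandpass(rnorm(nv), config$tr_seconds, 0.005, 0.1)
  resp <- 0.5 * sin(2 * pi * 0.3 * t_sec + runif(1, 0, 2 * pi))
  w <- slow / sd(slow) + resp
  (w - mean(w)) / sd(w)
}

#' Render a BOLD volume from neuronal drivers
#'
#' Every in-network voxel receives the hemodynamic expression of its network
#' driver scaled by the network amplitude, plus a slow physiological drift
#' common to all in-brain voxels and white voxel noise. White-matter, CSF and
#' vessel voxels carry drift and noise only. A venous waveform for later
#' confound injection is generated and attached as the attribute
#' `venous_waveform`.
#'
#' @param drivers Matrix from [make_neuronal_drivers()].
#' @param geometry Atlas/mask list from [make_atlas()].
#' @param vessel Vessel model from [make_vessel()].
#' @param config A [sim_config()].
#' @param participant_seed Integer seed for the stochastic components.
#' @param amplitude Per-network BOLD signal amplitudes (default
#'   `bold_signal_amp` for every network).
#' @return A [volume_series()] with `gray`, `white`, `csf`, `vessel` masks
#'   and the fBV map.
#' @export
render_bold <- function(drivers, geometry, vessel, config, participant_seed,
                        amplitude = NULL) {
  K <- config$n_networks
  if (nrow(drivers) != K) stop("shape error: driver count does not match the atlas")
  if (is.null(amplitude)) amplitude <- rep(config$bold_signal_amp, K)
  if (length(amplitude) != K) stop("shape error: one amplitude per network required")
  set.seed(as.integer(participant_seed))
  nv <- config$n_volumes
  d <- config$grid_dim
  hsig <- t(vapply(seq_len(K), function(k) driver_to_bold(drivers[k, ], config),
                   numeric(nv)))
  physio <- boxcar_bandpass(rnorm(nv), config$tr_seconds, 0.005, 0.08)
  physio <- if (sd(physio) > 0) physio / sd(physio) else physio
  venous <- make_venous_waveform(config)

  brain <- geometry$gray | geometry$white | geometry$csf | vessel$mask
  nvox <- prod(d)
  dat <- matrix(config$baseline, nvox, nv)
  bidx <- which(brain)
  dat[bidx, ] <- dat[bidx, ] +
    matrix(physio * 0.3, length(bidx), nv, byrow = TRUE) +
    config$noise_sd * matrix(rnorm(length(bidx) * nv), length(bidx), nv)
  atlas_vec <- as.integer(geometry$atlas)
  for (k in seq_len(K)) {
    vk <- which(atlas_vec == k)
    dat[vk, ] <- dat[vk, ] + matrix(amplitude[k] * hsig[k, ], length(vk), nv,
                                    byrow = TRUE)
  }
  v <- volume_series(array(dat, c(d, nv)), tr = config$tr_seconds,
                     masks = list(gray = geometry$gray, white = geometry$white,
                                  csf = geometry$csf, vessel = vessel$mask),
                     fbv = vessel$fbv)
  attr(v, "venous_waveform") <- venous
  v
}

#' Inject the macrovascular confound into a volume
#'
#' Adds `amplitude(v) * reference(t - lag(v))` to every voxel, where the
#' amplitude decays exponentially with the distance to the vessel at scale
#' `confound_decay` (and is exactly zero wherever fBV is zero) and the lag
#' grows with distance up to `max_confound_lag` frames. Lagged copies use the
#' edge-replicated shift of [shift_series()].
#'
#' @param volume A [volume_series()] (typically from [render_bold()]).
#' @param vessel Vessel model from [make_vessel()].
#' @param config A [sim_config()].
#' @param gain Venous gain for this participant (default
#'   `config$confound_amplitude`); 0 returns the input unchanged.
#' @param reference Venous waveform (default the volume's attached
#'   `venous_waveform`).
#' @return A new [volume_series()] with attribute `confound_field`, a list
#'   recording the exact per-voxel `amplitude` and `lag` arrays, the
#'   `reference` and the `gain`.
#' @export
inject_macrovascular_confound <- function(volume, vessel, config,
                                          gain = config$confound_amplitude,
                                          reference = NULL) {
  if (gain == 0) return(volume)
  if (is.null(reference)) reference <- attr(volume, "venous_waveform")
  if (is.null(reference)) stop("no venous reference waveform available")
  nv <- n_frames(volume)
  if (length(reference) != nv) stop("reference length does not match the series")
  if (config$max_confound_lag >= nv)
    stop("configuration error: confound lag exceeds the series length")
  amp <- gain * exp(-vessel$dist / config$confound_decay)
  amp[vessel$fbv == 0] <- 0
  lag <- pmin(floor(vessel$dist / 2), config$max_confound_lag)
  lag[amp == 0] <- 0L
  d <- grid_dim(volume)
  dat <- matrix(volume$data, prod(d), nv)
  for (l in sort(unique(lag[amp > 0]))) {
    idx <- which(amp > 0 & lag == l)
    dat[idx, ] <- dat[idx, ] +
      amp[idx] %o% shift_series(reference, l)
  }
  out <- volume_series(array(dat, c(d, nv)), tr = volume$tr,
                       masks = volume$masks, fbv = volume$fbv)
  attr(out, "venous_waveform") <- reference
  attr(out, "confound_field") <- list(amplitude = amp, lag = array(as.integer(lag), d),
                                      reference = reference, gain = gain)
  out
}

#' Generate a full synthetic cohort
#'
#' Draws balanced sex labels and per-participant latent neuronal amplitudes,
#' renders paired BOLD and EEG datasets sharing the same drivers, and (when
#' `confound_amplitude > 0`) injects the macrovascular confound with a
#' per-participant lognormal venous gain. All randomness derives from
#' `master_seed`, so identical configurations give bit-identical cohorts.
#'
#' @param config A [sim_config()].
#' @param eeg Logical; set `FALSE` to skip rendering source signals (the
#'   drivers are still generated and used for BOLD).
#' @return List with `participants` (each a list with `bold` and `eeg`),
#'   `atlas`, `geometry`, `vessel`, `truth` (ground-truth record of every
#'   injected parameter) and `config`.
#' @export
make_cohort <- function(config, eeg = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$master_seed)
  n <- config$n_participants
  K <- config$n_networks
  sex <- rep(c(1, -1), length.out = n)[sample.int(n)]
  latent <- rnorm(n)
  latents_nk <- latent + matrix(rnorm(n * K, sd = config$network_jitter), n, K)
  # gain noise is always drawn so that cohorts with and without the
  # confound share the same RNG stream (paired comparisons differ only in
  # the injected component)
  gain <- config$confound_amplitude * exp(rnorm(n, sd = config$confound_gain_sd))
  seeds <- matrix(derive_seeds(2L * n), n, 2L)

  geometry <- make_atlas(config)
  vessel <- make_vessel(config)
  amp <- matrix(NA_real_, n, K)
  participants <- vector("list", n)
  references <- vector("list", n)
  confound <- NULL
  for (i in seq_len(n)) {
    drivers <- make_neuronal_drivers(config, seeds[i, 1L], latents_nk[i, ])
    slope <- 0.5 * config$coupling_beta * (1 + config$sex_interaction * sex[i])
    amp[i, ] <- config$bold_signal_amp *
      exp(slope * latents_nk[i, ] + config$sex_main * sex[i])
    bold <- render_bold(drivers, geometry, vessel, config, seeds[i, 2L], amp[i, ])
    references[[i]] <- attr(bold, "venous_waveform")
    if (gain[i] > 0) {
      bold <- inject_macrovascular_confound(bold, vessel, config, gain[i])
      confound <- attr(bold, "confound_field")[c("amplitude", "lag")]
    }
    src <- if (eeg) render_sources(drivers, config) else NULL
    participants[[i]] <- list(bold = bold, eeg = src)
  }
  truth <- list(sex = sex, latent = latent, latents_network = latents_nk,
                bold_amplitude = amp, confound_gain = gain,
                confound_field = confound, references = references,
                coupling_beta = config$coupling_beta,
                sex_interaction = config$sex_interaction,
                sex_main = config$sex_main)
  list(participants = participants, atlas = geometry$atlas,
       geometry = geometry, vessel = vessel, truth = truth, config = config)
}

# EEG sources: each network contributes `sources_per_network` sources, the
# k-th a copy of the network driver delayed by 2(k-1) samples (16 ms at
# 125 Hz) plus independent sensor-level noise. The deterministic inter-source
# delay creates genuine (non-zero-lag) phase coupling within networks, which
# imaginary coherence is designed to detect. Uses the current RNG stream.
render_sources <- function(drivers, config) {
  K <- config$n_networks
  P <- config$sources_per_network
  n <- ncol(drivers)
  dat <- matrix(0, K * P, n)
  net <- integer(K * P)
  row <- 0L
  for (k in seq_len(K)) {
    for (p in seq_len(P)) {
      row <- row + 1L
      dat[row, ] <- shift_series(drivers[k, ], 2L * (p - 1L)) + 0.5 * rnorm(n)
      net[row] <- k
    }
  }
  source_signals(dat, rate = config$eeg_rate_hz, network = net)
}

#' Simulate network-wise metric tables directly
#'
#' Metric-level counterpart of [make_cohort()]: generates the long metric
#' tables the association stage consumes, with all effects specified on the
#' standardized scale so the ground-truth coupling slope is directly the
#' standardized fixed-effect coefficient the mixed model estimates. One
#' designated (Y, X) pair is coupled; every other metric is participant-
#' structured noise. Residual variance of the coupled Y is set to complement
#' the explained variance, keeping `Var(Y)` near 1.
#'
#' @param n_participants,n_networks Cohort design (defaults 20 and 7).
#' @param coupling_beta Standardized slope of the coupled pair (default 0.5).
#' @param sex_interaction Standardized X:Sex interaction (default 0.3).
#' @param sex_main Standardized sex main effect (default 0.1).
#' @param sigma_participant SD of the participant random intercept
#'   (default 0.3).
#' @param participant_share Share of X variance carried by the participant
#'   level (default 0.8; associations are inter-participant).
#' @param coupled_y,coupled_x Names of the coupled metrics (defaults
#'   `"rsfa"` and `"power_alpha"`).
#' @param states Correction states to emit for the fMRI table (default
#'   `"pre"`).
#' @param y_metrics,x_metrics Metric vocabularies (defaults
#'   [fmri_metric_names()] and [eeg_metric_names()]).
#' @param seed Optional integer seed.
#' @return List with `fmri` and `eeg` metric tables, `sex` labels
#'   (`data.frame(participant, sex)`), and the coupled pair.
#' @export
simulate_metric_cohort <- function(n_participants = 20L, n_networks = 7L,
                                   coupling_beta = 0.5, sex_interaction = 0.3,
                                   sex_main = 0.1, sigma_participant = 0.3,
                                   participant_share = 0.8,
                                   coupled_y = "rsfa", coupled_x = "power_alpha",
                                   states = "pre",
                                   y_metrics = fmri_metric_names(),
                                   x_metrics = eeg_metric_names(),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- n_participants
  K <- n_networks
  sex <- rep(c(1, -1), length.out = n)[sample.int(n)]
  pid <- rep(seq_len(n), each = K)
  nid <- rep(seq_len(K), times = n)
  sx <- sex[pid]

  xvals <- list()
  for (x in x_metrics) {
    lx <- rnorm(n)
    xvals[[x]] <- sqrt(participant_share) * lx[pid] +
      sqrt(1 - participant_share) * rnorm(n * K)
  }
  eeg <- do.call(rbind, lapply(x_metrics, function(x)
    metric_table(pid, nid, x, "eeg", NA_character_, xvals[[x]])))

  sig_e2 <- max(0.05, 1 - coupling_beta^2 * (1 + sex_interaction^2) -
                  sex_main^2 - sigma_participant^2)
  fmri <- NULL
  for (st in states) {
    for (y in y_metrics) {
      u <- rnorm(n, sd = sigma_participant)
      val <- if (y == coupled_y && coupled_x %in% x_metrics) {
        coupling_beta * (1 + sex_interaction * sx) * xvals[[coupled_x]] +
          sex_main * sx + u[pid] + rnorm(n * K, sd = sqrt(sig_e2))
      } else {
        u[pid] + rnorm(n * K, sd = sqrt(1 - sigma_participant^2))
      }
      fmri <- rbind(fmri, metric_table(pid, nid, y, "fmri", st, val))
    }
  }
  list(fmri = fmri, eeg = eeg,
       sex = data.frame(participant = seq_len(n), sex = sex),
       coupled = c(y = coupled_y, x = coupled_x))
}
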