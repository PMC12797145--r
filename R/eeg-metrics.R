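# EEG source metrics: fractional band power, normalized total power,
# imaginary coherence (band-limited and broadband) and the multiscale-
# entropy complexity index, reduced to network-wise values.

#' Remove the least-squares linear trend from every source
#'
#' @param s A [source_signals()] object.
#' @return A detrended [source_signals()] (each source has mean ~0).
#' @export
detrend_sources <- function(s) {
  n <- ncol(s$data)
  t0 <- seq_len(n) - (n + 1) / 2          # centered time regressor
  denom <- sum(t0^2)
  slope <- (s$data %*% t0) / denom
  s$data <- s$data - rowMeans(s$data) - slope %*% t0
  s
}

# Frequency bin selector on a folded frequency grid: half-open [low, high)
# except gamma which closes at 50 Hz.
band_bins <- function(f, low, high, closed_high = FALSE) {
  if (closed_high) f >= low & f <= high else f >= low & f < high
}

# Per-source raw periodogram band powers; returns the band-power matrix and
# the 1-50 Hz total.
source_band_power <- function(s, bands = band_scheme()) {
  n <- ncol(s$data)
  f <- (seq_len(n) - 1) * s$rate / n
  f <- pmin(f, s$rate - f)
  P <- abs(t(mvfft(t(s$data))))^2 / n
  bp <- sapply(seq_len(nrow(bands)), function(b)
    rowSums(P[, band_bins(f, bands$low[b], bands$high[b],
                          bands$band[b] == "gamma"), drop = FALSE]))
  bp <- matrix(bp, nrow = nrow(s$data),
               dimnames = list(NULL, bands$band))
  list(band = bp, total = rowSums(bp))
}

#' Fractional band power per source
#'
#' Fourier power integrated over each canonical band divided by the total
#' 1-50 Hz power. Fractions sum to 1 per source; an all-zero source yields a
#' missing row.
#'
#' @param s A (detrended) [source_signals()] object.
#' @param bands Band definition table (default [band_scheme()]).
#' @return Sources-by-bands matrix of fractions in `[0, 1]`.
#' @export
compute_fractional_power <- function(s, bands = band_scheme()) {
  bp <- source_band_power(s, bands)
  frac <- bp$band / bp$total
  frac[bp$total == 0, ] <- NA_real_
  frac
}

#' Spatially normalized total power per source
#'
#' Total 1-50 Hz power divided by the (sample) standard deviation of that
#' quantity across the participant's sources, absorbing inter-participant
#' SNR differences.
#'
#' @inheritParams compute_fractional_power
#' @return Numeric vector, one value per source (`NA` when the spatial SD is
#'   zero).
#' @export
compute_total_power <- function(s, bands = band_scheme()) {
  if (nrow(s$data) < 2L) stop("at least 2 sources are required")
  tot <- source_band_power(s, bands)$total
  spatial_sd <- sd(tot)
  if (spatial_sd == 0) return(rep(NA_real_, length(tot)))
  tot / spatial_sd
}

#' Welch cross-spectrum of a source pair
#'
#' Segment-averaged cross- and auto-spectra with Hann taper. The segment
#' length is `rate / delta_f` samples, giving the requested frequency
#' resolution; segments overlap by the given fraction.
#'
#' @param u,v Numeric series of equal length.
#' @param rate Sampling rate in Hz.
#' @param delta_f Frequency resolution in Hz (default 0.5).
#' @param overlap Segment overlap fraction in `[0, 1)` (default 0.5).
#' @return List with `freq`, complex `suv`, real `suu`, `svv`, and
#'   `n_segments`.
#' @export
compute_cross_spectrum <- function(u, v, rate, delta_f = 0.5, overlap = 0.5) {
  if (length(u) != length(v)) stop("series lengths differ")
  if (overlap < 0 || overlap >= 1) stop("`overlap` must lie in [0, 1)")
  L <- round(rate / delta_f)
  if (L > length(u)) stop("length error: series shorter than one segment")
  hop <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, length(u) - L + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, L - 1) / (L - 1)))  # Hann
  suv <- complex(real = rep(0, L))
  suu <- svv <- numeric(L)
  for (st in starts) {
    iu <- u[st:(st + L - 1L)] * w
    iv <- v[st:(st + L - 1L)] * w
    U <- fft(iu)
    V <- fft(iv)
    suv <- suv + U * Conj(V)
    suu <- suu + abs(U)^2
    svv <- svv + abs(V)^2
  }
  N <- length(starts)
  half <- seq_len(L %/% 2 + 1L)
  list(freq = (half - 1) * rate / L, suv = suv[half] / N,
       suu = suu[half] / N, svv = svv[half] / N, n_segments = N)
}

#' Imaginary coherence spectrum
#'
#' Magnitude of the imaginary part of the complex coherence
#' `S_uv / sqrt(S_uu S_vv)`, in `[0, 1]` per frequency bin; bins with a zero
#' auto-spectrum are flagged missing.
#'
#' @param sm A cross-spectrum from [compute_cross_spectrum()].
#' @return Numeric vector over `sm$freq`.
#' @export
compute_imaginary_coherence <- function(sm) {
  denom <- sqrt(sm$suu * sm$svv)
  out <- rep(NA_real_, length(denom))
  ok <- denom > 0
  out[ok] <- abs(Im(sm$suv[ok] / denom[ok]))
  out
}

#' Band-limited and broadband averages of a coherence spectrum
#'
#' Arithmetic mean of the spectrum over each band's bins, plus the broadband
#' mean over all 1-50 Hz bins.
#'
#' @param freq Frequency grid in Hz.
#' @param spectrum Values on `freq` (e.g. imaginary coherence).
#' @param bands Band definition table (default [band_scheme()]).
#' @return Named vector: one value per band plus `broadband`.
#' @export
band_coherence <- function(freq, spectrum, bands = band_scheme()) {
  out <- setNames(rep(NA_real_, nrow(bands) + 1L), c(bands$band, "broadband"))
  for (b in seq_len(nrow(bands))) {
    sel <- band_bins(freq, bands$low[b], bands$high[b], bands$band[b] == "gamma")
    if (!any(sel)) stop("configuration error: band '", bands$band[b],
                        "' has no frequency bins at this resolution")
    out[b] <- mean(spectrum[sel], na.rm = TRUE)
  }
  out["broadband"] <- mean(spectrum[freq >= 1 & freq <= 50], na.rm = TRUE)
  out
}

#' Within-network imaginary coherence
#'
#' Mean band-averaged imaginary coherence over all unordered within-network
#' source pairs. Networks with a single source are missing.
#'
#' @param s A [source_signals()] object.
#' @param bands Band definition table (default [band_scheme()]).
#' @param delta_f,overlap Welch parameters (defaults 0.5 Hz, 0.5).
#' @return Networks-by-(bands + broadband) matrix.
#' @export
network_coherence <- function(s, bands = band_scheme(), delta_f = 0.5,
                              overlap = 0.5) {
  nets <- sort(unique(s$network))
  out <- matrix(NA_real_, length(nets), nrow(bands) + 1L,
                dimnames = list(nets, c(bands$band, "broadband")))
  for (ni in seq_along(nets)) {
    src <- which(s$network == nets[ni])
    if (length(src) < 2L) next
    pairs <- utils::combn(src, 2L)
    acc <- matrix(0, ncol(pairs), nrow(bands) + 1L)
    for (p in seq_len(ncol(pairs))) {
      sm <- compute_cross_spectrum(s$data[pairs[1, p], ], s$data[pairs[2, p], ],
                                   s$rate, delta_f, overlap)
      acc[p, ] <- band_coherence(sm$freq, compute_imaginary_coherence(sm), bands)
    }
    out[ni, ] <- colMeans(acc)
  }
  out
}

#' Multiscale-entropy complexity index (CI)
#'
#' Coarse-grains the series at each scale (non-overlapping means), computes
#' sample entropy per scale with a tolerance fixed from the ORIGINAL series'
#' SD (the common multiscale convention, constant across scales), and
#' returns the trapezoidal area under the (scale, entropy) curve. With
#' `band`, the series is boxcar-filtered to that band first and the
#' tolerance taken from the filtered series.
#'
#' @param x Numeric series.
#' @param rate Sampling rate in Hz (required when `band` is given).
#' @param m Embedding length for the per-scale sample entropy (default 2).
#' @param r_factor Tolerance multiplier of the series SD (default 0.5).
#' @param scales Coarse-graining factors (default `c(3, 6, 13, 21, 62)`).
#' @param band Optional `c(low, high)` band in Hz.
#' @return CI value with attribute `entropy` (per-scale values); `NA` when
#'   any scale is too short (`length / max(scales) <= m + 1`).
#' @export
compute_complexity_index <- function(x, rate = NULL, m = 2L, r_factor = 0.5,
                                     scales = c(3, 6, 13, 21, 62),
                                     band = NULL) {
  if (!is.null(band)) {
    if (is.null(rate)) stop("`rate` is required for band-limited CI")
    x <- boxcar_bandpass(x, 1 / rate, band[1], band[2])
  }
  if (floor(length(x) / max(scales)) <= m + 1L) {
    out <- NA_real_
    attr(out, "required_length") <- (m + 2L) * max(scales)
    return(out)
  }
  r <- r_factor * sd(x)
  ent <- vapply(scales, function(tau) {
    ncg <- floor(length(x) / tau)
    cg <- colMeans(matrix(x[seq_len(ncg * tau)], nrow = tau))
    sampen_cpp(cg, as.integer(m), r)
  }, numeric(1))
  ci <- if (any(is.na(ent))) NA_real_ else trapz(scales, ent)
  attr(ci, "entropy") <- setNames(ent, scales)
  ci
}

#' Compute the network-wise EEG metric table for one participant
#'
#' Fractional band power, normalized total power and the complexity index
#' are computed per source and averaged within networks; imaginary coherence
#' is averaged over within-network source pairs. Sources carry their network
#' labels directly (synthetic data are generated in source space).
#'
#' @param s A [source_signals()] object.
#' @param participant Participant identifier for the output rows.
#' @param metrics Subset of [eeg_metric_names()] to compute.
#' @param detrend Apply [detrend_sources()] first (default TRUE).
#' @return A metric table (see [metric_table()]); state is `NA` (EEG metrics
#'   do not depend on the BOLD correction state).
#' @export
compute_eeg_metrics <- function(s, participant, metrics = eeg_metric_names(),
                                detrend = TRUE) {
  if (detrend) s <- detrend_sources(s)
  bands <- band_scheme()
  nets <- sort(unique(s$network))
  rows <- list()
  add <- function(metric, values)
    metric_table(participant, nets, metric, "eeg", NA_character_, values)
  net_mean <- function(x) vapply(nets, function(k)
    mean(x[s$network == k], na.rm = TRUE), numeric(1))

  power_names <- paste0("power_", bands$band)
  if (any(power_names %in% metrics)) {
    frac <- compute_fractional_power(s, bands)
    for (b in seq_len(nrow(bands))) {
      nm <- power_names[b]
      if (nm %in% metrics) rows[[nm]] <- add(nm, net_mean(frac[, b]))
    }
  }
  if ("power_total" %in% metrics)
    rows$power_total <- add("power_total", net_mean(compute_total_power(s, bands)))
  coh_names <- c(paste0("coh_", bands$band), "coh_broadband")
  if (any(coh_names %in% metrics)) {
    nc <- network_coherence(s, bands)
    for (j in seq_along(coh_names)) {
      nm <- coh_names[j]
      if (nm %in% metrics) rows[[nm]] <- add(nm, nc[, j])
    }
  }
  if ("ci" %in% metrics) {
    ci_src <- apply(s$data, 1L, function(x)
      as.numeric(compute_complexity_index(x)))
    rows$ci <- add("ci", net_mean(ci_src))
  }
  do.call(rbind, unname(rows))
}
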