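---
title: "Macrovascular correction and inter-participant EEG-fMRI coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Macrovascular correction and inter-participant EEG-fMRI coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macrovasc)
```

## The problem

Resting-state BOLD fluctuations are routinely interpreted as a hemodynamic
echo of the same neuronal activity that EEG measures directly. Large veins
complicate that interpretation: venous oxygenation fluctuations produce BOLD
signal of non-neuronal origin that spreads into perivascular tissue on the
centimetre scale, inflating amplitude and connectivity metrics in a spatially
structured way. If EEG and rs-fMRI metrics are compared across participants,
this macrovascular component acts as participant-level, metric-correlated
noise that attenuates and distorts the associations.

`macrovasc` implements the full analysis chain needed to study this problem
quantitatively:

1. **fMRI metrics** — resting-state fluctuation amplitude (RSFA), seed-based
   functional connectivity (FC), global and local functional connectivity
   density (gFCD/lFCD), and per-voxel sample entropy, reduced to
   network-wise values.
2. **EEG metrics** — fractional band power, spatially normalized total
   power, band-limited and broadband imaginary coherence, and the
   multiscale-entropy complexity index (CI).
3. **Macrovascular correction** — lag-optimized nuisance regression of a
   venous reference signal extracted from the maximum-fBV voxel.
4. **Association stage** — per metric pair, the linear mixed-effects model
   `Y ~ 1 + X + Sex + X:Sex` with a participant random intercept,
   z-transformed variables, 1.5 IQR outlier screening, Benjamini-Hochberg
   FDR control per correction state, and a paired Wilcoxon comparison of
   adjusted r² before vs after correction.
5. **A synthetic cohort generator** that makes every stage testable without
   access to human data.

## The synthetic cohort generator

No human data ship with this package, so the generator is a first-class
component: its defaults define the emulated study conditions — 20
participants (balanced sex), 7 functional networks, BOLD at TR 4.5 s with 53
frames (a 4-minute run), EEG source signals at 125 Hz for 240 s.

The generative model is deliberately the simplest structure that gives every
metric something real to measure:

* **Drivers.** Each network has one unit-variance Gaussian driver whose
  power spectrum mixes the five canonical bands (delta 1-4, theta 4-8,
  alpha 8-12, beta 12-30, gamma 30-50 Hz) with weights
  .10/.10/.50/.20/.10 plus a 10% flat 1-50 Hz floor. An alpha-dominant
  spectrum is the natural choice for resting-state-like activity.
* **The latent coupling variable.** A participant-by-network latent
  `l ~ N(0, 1)` (plus per-network jitter, SD 0.3) modulates the alpha band
  weight on the log scale (EEG side) and — scaled by the ground-truth slope
  `coupling_beta` and its sex modulation — the BOLD network amplitude (fMRI
  side). Fractional band power is scale-invariant, so an amplitude-only
  latent could not couple the modalities; routing it through the *band
  mixture* makes alpha fractional power the EEG expression of the latent,
  with RSFA (and the density metrics, via SNR) its fMRI expression.
* **EEG sources.** Each network contributes two sources: the driver delayed
  by 0 and 2 samples (16 ms) plus sensor noise. The deterministic delay
  creates genuine non-zero-lag phase coupling, which imaginary coherence is
  designed to detect while remaining blind to instantaneous mixing.
* **BOLD.** Each in-network voxel carries the rectified, low-passed driver
  envelope convolved with a canonical double-gamma kernel (peak 6 s,
  undershoot 16 s), sampled at the TR grid, at amplitude 1 (network signal)
  against unit-SD voxel noise and a weak common physiological drift. The
  amplitude/noise ratio was chosen so that within-network correlations sit
  near the 0.6 density threshold — density metrics respond to the latent and
  to the confound instead of saturating.
* **Geometry.** A 16³ voxel grid with seven 4³ network blobs at octant
  centres, white-matter and CSF blocks in the spare octant, and a straight
  vessel line through the middle; fBV decays exponentially from the vessel
  and is exactly zero beyond a 6-voxel dilation. Spatial units are voxels;
  no anatomical registration is simulated.
* **The macrovascular confound.** A venous waveform (low-pass < 0.1 Hz
  noise plus an aliased respiratory sinusoid) is added to every
  non-zero-fBV voxel as `amplitude(v) * reference(t - lag(v))`, with the
  amplitude decaying at scale 2.5 voxels (about 1 cm at common voxel sizes,
  matching the reported reach of perivascular bias) and the lag growing
  with distance up to 3 frames. The vessel-level gain is 3 (in voxel-noise
  SD units) with per-participant lognormal variability (log-SD 0.4): it is
  precisely the *between-participant* variability of venous contamination
  that corrupts inter-participant associations. The gain noise is drawn
  whether or not the confound is enabled, so confound-on and confound-off
  cohorts with the same seed are exactly paired.

Everything derives from `master_seed`; identical configurations give
bit-identical cohorts.

```{r, eval = FALSE}
cfg <- sim_config(master_seed = 1)
cohort <- make_cohort(cfg)
res <- run_full_analysis(cohort, out_dir = "run1")
res$r2_comparison
```

A second, metric-level simulator (`simulate_metric_cohort()`) generates the
network-wise metric tables directly, with all effects on the standardized
scale. It exists because the volumetric generator's coupling is injected
through a nonlinear chain (band weights, envelopes, ratios), so its
standardized regression slope is not numerically equal to `coupling_beta`;
the metric-level simulator is the right instrument for calibration questions
(slope recovery, interval coverage, type-I control of the grid), the
volumetric generator for pipeline questions (confound injection and
correction).

## What the generator does not emulate

Realistic vascular anatomy, field-strength or echo-time dependence, motion,
physiological recordings, and EEG forward/inverse modelling are all out of
scope; sources carry network labels directly. Passing tests therefore show
that the *analysis chain* behaves as specified under a known generative
model — not that real data satisfy that model.

## Numerical and procedural choices

* **Bandpass** is a frequency-domain boxcar (0.01-0.1 Hz for BOLD), an
  exact projection, hence idempotent; voxel means are restored after
  filtering so RSFA's denominator survives. The RSFA mean is taken from the
  unfiltered series, the SD from the filtered one.
* **Density metrics**: correlation threshold 0.6; lFCD grows clusters by
  face adjacency (6-connectivity) with correlations always computed against
  the index voxel, which is excluded from the count; constant series
  correlate with nothing. Densities are `log(1 + x)`-transformed voxelwise
  before network averaging (the zero-tolerant form of the log transform the
  exponential-like density distributions call for).
* **Sample entropy**: Chebyshev distance, matches at distance `<= r`,
  self-matches excluded, `m = 3`, `r = 0.6 * SD` for BOLD; a constant
  series yields 0, series with no matches are missing.
* **Welch spectra**: Hann taper, 0.5 Hz resolution, 50% overlap. Frequency
  bins belong to bands by half-open intervals `[low, high)` except gamma,
  which closes at 50 Hz.
* **Complexity index**: per-scale sample entropy with `m = 2` and
  `r = 0.5 * SD` of the original (or band-filtered) series, constant across
  scales — the common multiscale convention; scales 3, 6, 13, 21, 62;
  CI is the trapezoidal area under the entropy-scale curve. The broadband
  CI is the headline EEG complexity metric; band-limited CIs are available
  through the `band` argument.
* **Correction**: the reference is the max-fBV voxel's series, demeaned and
  peak-normalized (ties broken at the lowest linear index, with a warning);
  lags are searched in [-3, 3] frames (both signs — the direction of venous
  propagation is not assumed), ties resolved to the smallest `|lag|`,
  negative first; the lag-shifted reference (edge-replicated shift) is
  regressed out per voxel with an intercept, and the voxel mean restored.
  Because OLS residuals are exactly orthogonal to their regressors,
  re-applying a *fitted* model is a no-op; re-estimating from scratch on
  corrected data is not exactly idempotent, since residuals retain
  chance-level (`~1/sqrt(T)`) correlation with other lags of the reference.
* **Association stage**: variables are z-scored (sample SD; sex coded ±1
  then standardized), outliers removed per pair by the 1.5 IQR rule with
  type-7 quantiles, then re-standardized before fitting. The mixed model
  uses a participant random intercept by default (`random =
  "participant_network"` adds a network intercept); p-values are
  Satterthwaite t-tests. Adjusted r² is
  `1 - (1 - R2m) (n - 1) / (n - p - 1)` with `p = 3` and `R2m` the squared
  correlation between the observed response and the fixed-effects-only
  fitted values — a marginal (fixed-effects) goodness of fit. BH-FDR is
  applied separately within each correction state's family. The Wilcoxon
  signed-rank comparison of paired r² drops zero differences and uses the
  exact null up to 25 non-zero pairs (no ties), the continuity-corrected
  normal approximation otherwise.

## Interpreting the correction's effect on density metrics

Nuisance regression costs one degree of freedom per voxel and removes the
chance projection of genuine shared signal onto the reference. Both effects
push connectivity-density values slightly *below* what an untouched
confound-free dataset shows. When quantifying how far correction restores
confound-free values, the right baseline is therefore the confound-free
dataset passed through the same correction operator (a sham correction) —
the standard "process both arms identically" control. The package's property
tests use that control for the restoration comparison, and the unprocessed
baseline for the inflation comparison.

## Problem sizes used by the test suite

Unit tests run on reduced cohorts (1-6 participants, 26 BOLD frames, 120 s
EEG) chosen to exercise every code path quickly; the acceptance-style
property tests run at the full emulated study conditions: 20 x 7 design
counts, 100 replicates of 60-participant metric-level cohorts for interval
coverage, 20 null-grid replicates (65 metric pairs each), 50 volumetric
replicates for the post-correction r² gain of the coupled pair
(RSFA ~ alpha fractional power), and 20 paired volumetric seed pairs for
perivascular inflation and restoration.

## Known limitations

* The correction regressor has the same waveform at every voxel up to lag
  and gain — a single-reference approximation to a full per-voxel vascular
  simulation; it cannot capture voxel-specific venous waveform shapes.
* With 53 frames, sample entropy at `m = 3` and lag estimates are noisy;
  single-voxel results should not be over-read.
* The generator's coupling is monotone but nonlinear; standardized slopes
  from volumetric cohorts are not numerically equal to `coupling_beta`
  (use `simulate_metric_cohort()` when the slope itself is the question).
* EEG total power is normalized by the spatial SD across sources, so it is
  only defined for participants with at least two distinct sources.
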