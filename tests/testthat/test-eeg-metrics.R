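tone <- function(freq, n = 2500, rate = 125, phase = 0) {
  sin(2 * pi * freq * (0:(n - 1)) / rate + phase)
}

test_that("linear detrending removes ramps and preserves oscillations", {
  n <- 1000
  ramp <- seq(0, 5, length.out = n)
  # sinusoid with its own tiny linear component projected out, so the
  # detrending projection should return it untouched
  osc <- unname(residuals(lm(tone(10, n) ~ seq_len(n))))
  s <- src_set(list(ramp, osc, ramp + osc))
  out <- detrend_sources(s)
  expect_lt(max(abs(out$data[1, ])), 1e-9)
  expect_lt(max(abs(out$data[2, ] - osc)), 1e-6)
  expect_lt(max(abs(out$data[3, ] - osc)), 1e-6)
  expect_lt(abs(mean(out$data[3, ])), 1e-10)
})

test_that("fractional power resolves tones, splits equal tones, and sums to one", {
  s <- src_set(list(tone(10), tone(2) + tone(40)))
  fr <- compute_fractional_power(s)
  expect_gt(fr[1, "alpha"], 0.99)
  expect_true(all(fr[1, c("delta", "theta", "beta", "gamma")] < 0.01))
  expect_equal(unname(fr[2, "delta"]), 0.5, tolerance = 0.01)
  expect_equal(unname(fr[2, "gamma"]), 0.5, tolerance = 0.01)
  set.seed(5)
  s2 <- src_set(lapply(1:4, function(i) rnorm(3000)))
  fr2 <- compute_fractional_power(s2)
  expect_true(all(abs(rowSums(fr2) - 1) < 1e-6))
})

test_that("white-noise band fractions are proportional to bandwidth", {
  fracs <- t(vapply(1:30, function(seed) {
    set.seed(seed)
    colMeans(compute_fractional_power(src_set(list(rnorm(4000)))))
  }, numeric(5)))
  widths <- c(3, 4, 4, 18, 20) / 49
  expect_equal(unname(colMeans(fracs)), widths, tolerance = 0.02)
})

test_that("total power normalization matches the arithmetic oracle and its conventions", {
  set.seed(8)
  rows <- list(rnorm(2000), 2 * rnorm(2000), 0.5 * rnorm(2000))
  s <- src_set(rows)
  # independent oracle: periodogram total over 1-50 Hz per source
  n <- 2000
  f <- pmin((0:(n - 1)) * 125 / n, 125 - (0:(n - 1)) * 125 / n)
  totals <- vapply(rows, function(x) sum((abs(fft(x))^2 / n)[f >= 1 & f <= 50]),
                   numeric(1))
  expect_equal(unname(compute_total_power(s)), unname(totals / sd(totals)),
               tolerance = 1e-10)
  # scale cancellation
  s3 <- src_set(lapply(rows, function(x) 7 * x))
  expect_equal(compute_total_power(s3), compute_total_power(s), tolerance = 1e-10)
  # degenerate: identical sources have zero spatial SD
  s4 <- src_set(list(rows[[1]], rows[[1]]))
  expect_true(all(is.na(compute_total_power(s4))))
})

test_that("the Welch cross-spectrum behaves on identity, tones and independent noise", {
  set.seed(13)
  u <- rnorm(2500)
  sm <- compute_cross_spectrum(u, u, 125)
  expect_true(all(abs(Im(sm$suv)) < 1e-8))
  expect_true(all(Re(sm$suv) >= -1e-12))
  expect_equal(Re(sm$suv), sm$suu, tolerance = 1e-10)
  expect_equal(sm$freq[2] - sm$freq[1], 0.5)

  x <- tone(10); y <- tone(10, phase = 1)
  smt <- compute_cross_spectrum(x, y, 125)
  expect_equal(smt$freq[which.max(abs(smt$suv))], 10)

  hits <- vapply(1:10, function(seed) {
    set.seed(seed)
    a <- rnorm(2500); b <- rnorm(2500)
    smn <- compute_cross_spectrum(a, b, 125)
    mean(abs(smn$suv) / sqrt(smn$suu * smn$svv) < 0.5)
  }, numeric(1))
  expect_gt(mean(hits), 0.9)
  expect_error(compute_cross_spectrum(rnorm(100), rnorm(100), 125), "length")
})

test_that("imaginary coherence is zero for identical signals and one for quadrature pairs", {
  set.seed(17)
  u <- rnorm(2500)
  ic <- compute_imaginary_coherence(compute_cross_spectrum(u, u, 125))
  expect_true(all(ic[is.finite(ic)] < 1e-8))

  x <- tone(10) + 0.05 * rnorm(2500)
  y <- tone(10, phase = pi / 2) + 0.05 * rnorm(2500)
  sm <- compute_cross_spectrum(x, y, 125)
  ic2 <- compute_imaginary_coherence(sm)
  expect_gte(ic2[sm$freq == 10], 0.95)
  expect_true(all(ic2 >= 0 & ic2 <= 1, na.rm = TRUE))
  # symmetry in the pair order
  ic3 <- compute_imaginary_coherence(compute_cross_spectrum(y, x, 125))
  expect_equal(ic2, ic3, tolerance = 1e-10)
})

test_that("zero-lag mixtures of shared sources show only chance-level imaginary coherence", {
  set.seed(19)
  s1 <- rnorm(2500); s2 <- rnorm(2500)
  u <- 0.8 * s1 + 0.6 * s2       # two different instantaneous mixtures
  v <- 0.3 * s1 + 0.9 * s2
  sm <- compute_cross_spectrum(u, v, 125)
  obs <- mean(compute_imaginary_coherence(sm), na.rm = TRUE)
  # phase-randomized surrogate null for v
  nv <- length(v)
  null <- vapply(1:100, function(i) {
    ph <- fft(v)
    k <- 2:(nv %/% 2)
    rot <- exp(1i * runif(length(k), 0, 2 * pi))
    ph[k] <- ph[k] * rot
    ph[nv + 2 - k] <- Conj(ph[k])
    vs <- Re(fft(ph, inverse = TRUE)) / nv
    mean(compute_imaginary_coherence(compute_cross_spectrum(u, vs, 125)), na.rm = TRUE)
  }, numeric(1))
  expect_lt(obs, quantile(null, 0.95))
})

test_that("band averaging matches hand-computed means and flags empty bands", {
  freq <- seq(0, 62, by = 0.5)
  flat <- rep(0.3, length(freq))
  bc <- band_coherence(freq, flat)
  expect_true(all(abs(bc - 0.3) < 1e-12))

  alpha_only <- ifelse(freq >= 8 & freq < 12, 0.7, 0)
  bc2 <- band_coherence(freq, alpha_only)
  expect_equal(unname(bc2["alpha"]), 0.7)
  expect_true(all(bc2[c("delta", "theta", "beta", "gamma")] == 0))

  set.seed(23)
  spec <- runif(length(freq))
  bc3 <- band_coherence(freq, spec)
  hand_beta <- mean(spec[freq >= 12 & freq < 30])
  hand_gamma <- mean(spec[freq >= 30 & freq <= 50])
  hand_broad <- mean(spec[freq >= 1 & freq <= 50])
  expect_equal(unname(bc3["beta"]), hand_beta)
  expect_equal(unname(bc3["gamma"]), hand_gamma)
  expect_equal(unname(bc3["broadband"]), hand_broad)

  expect_error(band_coherence(seq(0, 50, by = 10), flat[1:6]), "configuration")
})

test_that("network coherence averages all within-network pairs and ignores source order", {
  set.seed(29)
  mk <- function() rnorm(2000)
  a <- mk(); b <- mk(); c <- mk()
  s3 <- source_signals(rbind(a, b, c), 125, c(1L, 1L, 1L))
  nc <- network_coherence(s3)
  pair_val <- function(u, v) {
    sm <- compute_cross_spectrum(u, v, 125)
    band_coherence(sm$freq, compute_imaginary_coherence(sm))
  }
  hand <- (pair_val(a, b) + pair_val(a, c) + pair_val(b, c)) / 3
  expect_equal(nc[1, ], hand, tolerance = 1e-10)

  s2 <- source_signals(rbind(a, b), 125, c(1L, 1L))
  expect_equal(network_coherence(s2)[1, ], pair_val(a, b), tolerance = 1e-10)

  sp <- source_signals(rbind(c, a, b), 125, c(1L, 1L, 1L))
  expect_equal(network_coherence(sp)[1, ], nc[1, ], tolerance = 1e-10)

  s1 <- source_signals(rbind(a, b), 125, c(1L, 2L))
  expect_true(all(is.na(network_coherence(s1))))
})

test_that("the complexity index obeys its conventions and scale-1 consistency", {
  const <- rep(1, 1000)
  ci0 <- compute_complexity_index(const, scales = c(1, 2, 4))
  expect_equal(as.numeric(ci0), 0)
  expect_true(all(attr(ci0, "entropy") == 0))

  set.seed(31)
  x <- rnorm(400)
  ci1 <- compute_complexity_index(x, scales = c(1, 2))
  e1 <- attr(ci1, "entropy")[["1"]]
  expect_equal(e1, naive_sampen(x, 2, 0.5 * sd(x)), tolerance = 1e-12)

  # amplitude-rescaling invariance (tolerance scales with the SD)
  ci_a <- compute_complexity_index(x, scales = c(2, 4, 8))
  ci_b <- compute_complexity_index(5 * x, scales = c(2, 4, 8))
  expect_equal(as.numeric(ci_a), as.numeric(ci_b), tolerance = 1e-10)

  # insufficient length at the largest scale is flagged, with the required length
  short <- compute_complexity_index(rnorm(100), scales = c(3, 62))
  expect_true(is.na(short))
  expect_gt(attr(short, "required_length"), 100)
})

test_that("white noise is more entropic than a strongly autocorrelated AR(1) at small scales", {
  wins <- vapply(1:20, function(seed) {
    set.seed(seed)
    w <- rnorm(3000)
    a <- as.numeric(stats::arima.sim(list(ar = 0.95), 3000))
    a <- a / sd(a)
    ew <- attr(compute_complexity_index(w, scales = c(3, 6)), "entropy")[["3"]]
    ea <- attr(compute_complexity_index(a, scales = c(3, 6)), "entropy")[["3"]]
    ew > ea
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("the per-participant EEG metric table is complete and order invariant", {
  cfg <- small_cfg()
  coh <- make_cohort(cfg)
  s <- coh$participants[[1]]$eeg
  tab <- compute_eeg_metrics(s, 1, metrics = c("power_alpha", "coh_alpha", "power_total"))
  expect_identical(nrow(tab), 3L * cfg$n_networks)
  expect_true(all(is.finite(tab$value)))
  perm <- sample(nrow(s$data))
  sp <- source_signals(s$data[perm, ], s$rate, s$network[perm])
  tabp <- compute_eeg_metrics(sp, 1, metrics = c("power_alpha", "coh_alpha", "power_total"))
  expect_equal(tab$value, tabp$value, tolerance = 1e-10)
})
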