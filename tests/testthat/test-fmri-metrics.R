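make_preproc_volume <- function(gray_series, n = 128, tr = 1, seed = 1) {
  # gray voxels as given plus noisy white-matter and CSF blocks
  set.seed(seed)
  wm <- replicate(3, 100 + rnorm(n, sd = 0.5))
  csf <- replicate(3, 100 + rnorm(n, sd = 0.5))
  y <- cbind(gray_series, wm, csf)
  V <- ncol(y)
  dims <- c(V, 1L, 1L)
  g <- array(FALSE, dims); g[seq_len(ncol(gray_series))] <- TRUE
  w <- array(FALSE, dims); w[ncol(gray_series) + 1:3] <- TRUE
  cs <- array(FALSE, dims); cs[ncol(gray_series) + 4:6] <- TRUE
  vol_from_matrix(y, dims, tr = tr, masks = list(gray = g, white = w, csf = cs))
}

test_that("bandpass preprocessing keeps in-band tones and kills out-of-band tones", {
  n <- 200; t <- 0:(n - 1)  # 0.05 and 0.2 Hz sit exactly on the FFT grid
  inband <- 100 + sin(2 * pi * 0.05 * t)
  outband <- 100 + sin(2 * pi * 0.2 * t)
  # the boxcar filter itself is exact on on-grid tones
  expect_equal(sd(boxcar_bandpass(inband, 1, 0.01, 0.1)),
               sd(inband - mean(inband)), tolerance = 1e-10)
  expect_lt(max(abs(boxcar_bandpass(outband, 1, 0.01, 0.1))), 1e-10)
  # the full preprocessing additionally regresses noisy WM/CSF means, which
  # perturbs amplitudes by the chance tone/noise overlap (~1-2% here)
  v <- make_preproc_volume(cbind(inband, outband), n = n, tr = 1)
  out <- preprocess_bold(v, band = c(0.01, 0.1))
  y <- voxel_matrix(out, out$masks$gray)
  amp_in <- sd(y[, 1]) / sd(inband - mean(inband))
  expect_equal(amp_in, 1, tolerance = 0.02)
  expect_lt(sd(y[, 2]), 0.03 * sd(outband - mean(outband)))
})

test_that("a voxel equal to the white-matter mean is regressed to (near) zero", {
  n <- 128
  set.seed(3)
  filler <- 100 + matrix(rnorm(n * 2, sd = 0.5), n, 2)
  v <- make_preproc_volume(filler, n = n)
  wm_mean <- rowMeans(voxel_matrix(v, v$masks$white))
  y <- voxel_matrix(v, v$masks$gray)
  y[, 1] <- wm_mean
  v <- set_voxel_matrix(v, v$masks$gray, y)
  out <- preprocess_bold(v)
  resid <- voxel_matrix(out, out$masks$gray)[, 1]
  expect_lt(sd(resid), 1e-10)
})

test_that("preprocessing validates masks and length", {
  n <- 128
  v <- make_preproc_volume(matrix(100 + rnorm(n), n, 1), n = n)
  v$masks$white[] <- FALSE
  expect_error(preprocess_bold(v), "white-matter")
  v2 <- make_preproc_volume(matrix(100 + rnorm(n), n, 1), n = n)
  expect_error(preprocess_bold(v2, drop_initial = n - 4), "length")
})

test_that("the boxcar bandpass is an idempotent projection", {
  set.seed(7)
  x <- matrix(rnorm(200 * 3), 200, 3)
  once <- boxcar_bandpass(x, 1, 0.01, 0.1)
  twice <- boxcar_bandpass(once, 1, 0.01, 0.1)
  expect_equal(once, twice, tolerance = 1e-12)
})

test_that("RSFA matches its closed form and is scale invariant", {
  n <- 400; t <- 0:(n - 1)
  s <- 100 + 10 * sin(2 * pi * 8 * t / n)  # integer cycles
  v <- vol_from_matrix(cbind(s, rep(50, n), -1 * s), c(3, 1, 1))
  r <- compute_rsfa(v)
  expect_equal(r[1], (10 / sqrt(2)) / 100, tolerance = 3e-3)
  expect_equal(r[2], 0)                       # constant voxel
  expect_true(is.na(r[3]))                    # negative-mean voxel flagged
  v3 <- vol_from_matrix(cbind(3 * s), c(1, 1, 1))
  expect_equal(compute_rsfa(v3)[1], r[1], tolerance = 1e-12)
})

test_that("gFCD matches constructions and the brute-force oracle exactly", {
  n <- 40
  set.seed(11)
  base <- rnorm(n)
  ident <- vol_from_matrix(cbind(base, base, base), c(3, 1, 1))
  expect_equal(as.vector(compute_gfcd(ident)[1:3]), c(2, 2, 2))

  # mutually orthogonal series
  o1 <- rnorm(n); o2 <- orthogonalize(rnorm(n), o1)
  orth <- vol_from_matrix(cbind(o1, o2), c(2, 1, 1))
  expect_equal(as.vector(compute_gfcd(orth, 0.6)[1:2]), c(0, 0))

  for (seed in 1:5) {
    set.seed(seed)
    y <- matrix(rnorm(n * 20), n, 20)
    y[, 2] <- y[, 1] + 0.3 * rnorm(n)  # guarantee some edges
    y[, 5] <- rep(1, n)                # constant voxel correlates with nothing
    v <- vol_from_matrix(y, c(5, 2, 2))
    got <- compute_gfcd(v, 0.6)[seq_len(20)]
    expect_identical(as.integer(got), brute_gfcd(y, 0.6))
  }
})

test_that("lFCD follows cluster growth from the index voxel", {
  n <- 60
  set.seed(21)
  x <- rnorm(n)
  mk <- function(r_target) x * r_target + orthogonalize(rnorm(n), x) * sqrt(1 - r_target^2)
  # chain of 4 voxels; all correlate with the first above 0.6
  y <- cbind(x, mk(0.9), mk(0.8), mk(0.85))
  v <- vol_from_matrix(y, c(4, 1, 1))
  l <- compute_lfcd(v, 0.6)
  expect_equal(l[1, 1, 1], 3)
  # a broken chain: middle voxel uncorrelated with the index voxel blocks growth
  y2 <- cbind(x, mk(0.9), orthogonalize(rnorm(n), x), mk(0.9))
  v2 <- vol_from_matrix(y2, c(4, 1, 1))
  expect_equal(compute_lfcd(v2, 0.6)[1, 1, 1], 1)
  # voxel with no qualifying neighbours
  expect_equal(compute_lfcd(v2, 0.6)[3, 1, 1], 0)
})

test_that("lFCD equals the flood-fill oracle and never exceeds gFCD", {
  n <- 50
  for (seed in 1:8) {
    set.seed(seed)
    y <- matrix(rnorm(n * 20), n, 20)
    y[, 3] <- y[, 2] + 0.25 * rnorm(n)
    y[, 7] <- y[, 2] + 0.25 * rnorm(n)
    dims <- c(5, 2, 2)
    v <- vol_from_matrix(y, dims)
    coords <- which(array(TRUE, dims), arr.ind = TRUE)
    lf <- as.integer(compute_lfcd(v, 0.6)[seq_len(20)])
    gf <- as.integer(compute_gfcd(v, 0.6)[seq_len(20)])
    expect_identical(lf, brute_lfcd(y, coords, 0.6))
    expect_true(all(lf <= gf))
  }
})

test_that("sample entropy equals the naive template-counting oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    x <- rnorm(50)
    for (m in c(2L, 3L)) {
      r <- 0.6 * sd(x)
      expect_equal(sample_entropy(x, m = m, r = r), naive_sampen(x, m, r),
                   tolerance = 1e-12)
    }
  }
  set.seed(99)
  x200 <- rnorm(200)
  expect_equal(sample_entropy(x200, m = 2, r = 0.5 * sd(x200)),
               naive_sampen(x200, 2, 0.5 * sd(x200)), tolerance = 1e-12)
})

test_that("sample entropy conventions: constant series, short series, regularity ordering", {
  expect_equal(sample_entropy(rep(2.5, 60)), 0)
  expect_true(is.na(sample_entropy(rnorm(4), m = 3)))
  orderings <- vapply(1:20, function(seed) {
    set.seed(seed)
    saw <- rep(seq(-1, 1, length.out = 15), 20)
    shuf <- sample(saw)
    r <- 0.5 * sd(saw)
    sample_entropy(saw, m = 2, r = r) < sample_entropy(shuf, m = 2, r = r)
  }, logical(1))
  expect_true(all(orderings))
})

test_that("seed-based FC covers the degenerate cap, orthogonal and closed-form cases", {
  n <- 80
  set.seed(31)
  x <- rnorm(n)
  atlas <- array(0L, c(4, 1, 1))
  atlas[1:2] <- 1L
  # network identical to seed: capped Fisher z
  v <- vol_from_matrix(cbind(x, x, rnorm(n), rnorm(n)), c(4, 1, 1))
  fc <- compute_seed_fc(v, atlas, seeds = list(`1` = 1L))
  expect_equal(unname(fc["1"]), atanh(0.999))
  # orthogonal network
  y <- orthogonalize(rnorm(n), x)
  v2 <- vol_from_matrix(cbind(x, y, rnorm(n), rnorm(n)), c(4, 1, 1))
  fc2 <- compute_seed_fc(v2, atlas, seeds = list(`1` = 1L))
  expect_equal(unname(fc2["1"]), 0, tolerance = 1e-10)
  # exact r = 0.5 pair
  z <- 0.5 * x + sqrt(0.75) * orthogonalize(rnorm(n), x) * sd(x)
  v3 <- vol_from_matrix(cbind(x, z, rnorm(n), rnorm(n)), c(4, 1, 1))
  fc3 <- compute_seed_fc(v3, atlas, seeds = list(`1` = 1L))
  expect_equal(unname(fc3["1"]), atanh(0.5), tolerance = 1e-10)
})

test_that("network summaries average correctly, with the zero-tolerant log", {
  atlas <- array(0L, c(4, 1, 1))
  atlas[1:4] <- c(1L, 1L, 2L, 2L)
  map <- array(c(3, 3, 0, 3), c(4, 1, 1))
  plain <- summarize_network(map, atlas)
  expect_equal(unname(plain["1"]), 3)
  logd <- summarize_network(map, atlas, log_transform = TRUE)
  expect_equal(unname(logd["1"]), log(4))
  expect_equal(unname(logd["2"]), mean(c(log(1), log(4))))
  zeros <- summarize_network(array(0, c(4, 1, 1)), atlas, log_transform = TRUE)
  expect_equal(unname(zeros["1"]), 0)
})
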