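# Independent brute-force oracles used to pin down the metric
# implementations on small instances. Deliberately written in the most
# literal style possible, sharing no code with the package internals.

# Sample entropy by exhaustive template comparison (Chebyshev, <= r,
# self-matches excluded, template starts 1..n-m for both lengths).
naive_sampen <- function(x, m, r) {
  n <- length(x)
  if (n <= m + 1) return(NA_real_)
  nm <- n - m
  A <- 0L
  B <- 0L
  for (i in seq_len(nm - 1)) {
    for (j in (i + 1):nm) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1L
      }
    }
  }
  if (B == 0L || A == 0L) return(NA_real_)
  -log(A / B)
}

# gFCD by exhaustive pairwise correlation (constant series correlate with
# nothing).
brute_gfcd <- function(y, threshold) {
  V <- ncol(y)
  counts <- integer(V)
  for (i in seq_len(V)) {
    for (j in seq_len(V)) {
      if (i == j) next
      if (sd(y[, i]) == 0 || sd(y[, j]) == 0) next
      if (cor(y[, i], y[, j]) >= threshold) counts[i] <- counts[i] + 1L
    }
  }
  counts
}

# lFCD by repeated-scan flood fill: grow the cluster from i by rescanning
# all voxels until no face-adjacent voxel correlated with i can be added.
brute_lfcd <- function(y, coords, threshold) {
  V <- ncol(y)
  adj <- function(a, b) sum(abs(coords[a, ] - coords[b, ])) == 1
  counts <- integer(V)
  for (i in seq_len(V)) {
    cluster <- i
    repeat {
      added <- FALSE
      for (j in seq_len(V)) {
        if (j %in% cluster) next
        if (!any(vapply(cluster, function(cc) adj(cc, j), logical(1)))) next
        if (sd(y[, i]) == 0 || sd(y[, j]) == 0) next
        if (cor(y[, i], y[, j]) >= threshold) {
          cluster <- c(cluster, j)
          added <- TRUE
        }
      }
      if (!added) break
    }
    counts[i] <- length(cluster) - 1L
  }
  counts
}

# Benjamini-Hochberg step-up by the textbook definition.
bh_stepup <- function(p, q) {
  n <- length(p)
  if (!n) return(logical(0))
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= q * seq_len(n) / n)
  flags <- rep(FALSE, n)
  if (length(k)) flags[o[seq_len(max(k))]] <- TRUE
  flags
}
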