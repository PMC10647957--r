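# Independent oracles used across the suite. These deliberately use naive
# nested-loop / brute-force computations so they share no code with the
# package's vectorized implementations.

# Hard-count joint histogram by explicit per-pixel loop, with the same
# epsilon-widened per-image ranges and nearest-center binning the soft
# histogram converges to as its bandwidth shrinks.
oracle_hard_joint <- function(a, b, n_bins) {
  widen <- function(v) {
    lo <- min(v); hi <- max(v)
    pad <- 1e-6 * (hi - lo) + 1e-12
    c(lo - pad, hi + pad)
  }
  ra <- widen(a); rb <- widen(b)
  bin_of <- function(v, r) {
    j <- floor((v - r[1]) / (r[2] - r[1]) * n_bins)
    min(max(j, 0), n_bins - 1) + 1L
  }
  P <- matrix(0, n_bins, n_bins)
  av <- as.vector(a); bv <- as.vector(b)
  for (k in seq_along(av)) {
    i <- bin_of(av[k], ra); j <- bin_of(bv[k], rb)
    P[i, j] <- P[i, j] + 1
  }
  P / length(av)
}

oracle_mi_bits <- function(P) {
  p <- rowSums(P); q <- colSums(P)
  s <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    if (P[i, j] > 0) s <- s + P[i, j] * log2(P[i, j] / (p[i] * q[j]))
  }
  s
}

oracle_entropy_bits <- function(p) {
  s <- 0
  for (v in p) if (v > 0) s <- s - v * log2(v)
  s
}

# Per-pixel affine displacement: loop over every pixel applying
# A (x - c) + c + t - x.
oracle_affine_field <- function(params, h, w, center = TRUE) {
  p <- unclass(params)
  A <- matrix(p[1:4], 2, 2, byrow = TRUE)
  t <- p[5:6]
  c0 <- if (center) c((h - 1) / 2, (w - 1) / 2) else c(0, 0)
  f <- array(0, c(h, w, 2))
  for (i in seq_len(h)) for (j in seq_len(w)) {
    x <- c(i - 1, j - 1)
    f[i, j, ] <- A %*% (x - c0) + c0 + t - x
  }
  f
}

# Exhaustive max-min Hausdorff over all point pairs.
oracle_hausdorff <- function(pa, pb) {
  dmin_a <- apply(pa, 1, function(p)
    min(apply(pb, 1, function(q) sqrt(sum((p - q)^2)))))
  dmin_b <- apply(pb, 1, function(p)
    min(apply(pa, 1, function(q) sqrt(sum((p - q)^2)))))
  max(max(dmin_a), max(dmin_b))
}

# Smooth multi-blob image for gradient checks (fractional centers keep
# sample positions away from the bilinear kink at integer coordinates).
smooth_test_image <- function(n = 24) {
  outer(0:(n - 1), 0:(n - 1), function(r, c)
    exp(-((r - n * 0.43)^2 + (c - n * 0.55)^2) / (n * 1.7)) +
      0.6 * exp(-((r - n * 0.68)^2 + (c - n * 0.31)^2) / n))
}

# A small aligned multimodal pair (identity truth) built directly from the
# generator's pieces.
aligned_phantom <- function(size = 64, seed = 5, tumor = TRUE) {
  make_pair(phantom_spec(size = size, tumor = tumor),
            affine_ranges(translation = 0, rotation = 0,
                          scale = c(1, 1), shear = 0),
            seed = seed)
}
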