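# Shared fixtures and independent oracles used across test files.

# Truncated-at-zero normal sample (independent of the package's internal).
r_tnorm0 <- function(n, mu, sigma) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * n, mu, sigma)
    out <- c(out, x[x >= 0])
  }
  out[seq_len(n)]
}

# Brute-force Kapur criterion: exhaustive search over all histogram cuts.
oracle_max_entropy_cut <- function(counts) {
  p <- counts / sum(counts)
  best <- -Inf; best_t <- NA
  for (t in seq_len(length(p) - 1)) {
    pt <- sum(p[1:t])
    if (pt <= 0 || pt >= 1) next
    pb <- p[1:t] / pt
    pf <- p[(t + 1):length(p)] / (1 - pt)
    h <- -sum(pb[pb > 0] * log(pb[pb > 0])) -
      sum(pf[pf > 0] * log(pf[pf > 0]))
    if (h > best) { best <- h; best_t <- t }
  }
  best_t
}

# Brute-force nearest-neighbor distances A -> B.
oracle_nearest_distances <- function(a, b) {
  apply(a, 1, function(p) min(sqrt(colSums((t(b) - p)^2))))
}

# Render a stack containing Gaussian blobs at given positions (nm relative
# to nucleus center), on a small nucleus for speed.
small_blob_sim <- function(positions, seed = 1, noise_level = 0,
                           intensity = 100, channel = 1) {
  cfg <- sim_config(seed = seed, nucleus_radii = c(800, 800, 600),
                    noise_level = noise_level)
  loci <- data.frame(x_nm = positions[, 1], y_nm = positions[, 2],
                     z_nm = positions[, 3], channel = channel,
                     intensity = intensity)
  generate_nucleus_stack(cfg, loci)
}

expect_equal_tol <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)), tol)
}
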