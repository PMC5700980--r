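test_that("nucleus segmentation recovers the ellipsoid volume", {
  zero <- voxel_stack(array(0, c(8, 20, 20)))
  expect_error(segment_nucleus(zero), "no nucleus found")

  # hard ellipsoid of intensity 100 on zero background
  hard_ellipsoid <- function(noise_sd = 0, seed = 1) {
    nz <- 16; ny <- 46; nx <- 46
    vxy <- 39.5; vz <- 125
    rad <- c(700, 700, 600)
    zc <- (seq_len(nz) - 0.5) * vz - nz * vz / 2
    yc <- (seq_len(ny) - 0.5) * vxy - ny * vxy / 2
    xc <- (seq_len(nx) - 0.5) * vxy - nx * vxy / 2
    rn2 <- outer(outer((zc / rad[3])^2, (yc / rad[2])^2, `+`),
                 (xc / rad[1])^2, `+`)
    arr <- ifelse(rn2 <= 1, 100, 0)
    if (noise_sd > 0) {
      set.seed(seed)
      arr <- pmax(arr + rnorm(length(arr), 0, noise_sd), 0)
    }
    list(stack = voxel_stack(array(arr, dim = c(nz, ny, nx)), vxy, vz,
                             "dapi"),
         volume = 4 / 3 * pi * prod(rad) / 1e9)
  }
  he <- hard_ellipsoid()
  mask <- segment_nucleus(he$stack)
  expect_lt(abs(mask$volume_um3 - he$volume) / he$volume, 0.05)
  expect_identical(dim(mask$mask), dim(he$stack$intensities))

  # 10% noise moves the volume by < 10%
  maskn <- segment_nucleus(hard_ellipsoid(noise_sd = 10, seed = 11)$stack)
  expect_lt(abs(maskn$volume_um3 - mask$volume_um3) / mask$volume_um3,
            0.10)

  expect_error(segment_nucleus(he$stack, roi = c(0, 5, 1, 5)), "ROI")
})

test_that("maximum-entropy threshold matches the brute-force oracle", {
  two <- c(rep(10, 990), rep(200, 10))
  thr <- max_entropy_threshold(two)
  expect_gt(thr, 10); expect_lt(thr, 200)

  # 8-level toy histogram, exhaustive cut search as oracle
  counts <- c(40, 30, 10, 5, 2, 8, 3, 2)
  vals <- rep(seq(0, 7), counts)  # values 0..7 hit 8 equal-width bins
  thr8 <- max_entropy_threshold(vals, n_bins = 8)
  cut8 <- findInterval(thr8, seq(0, 7, length.out = 9),
                       rightmost.closed = TRUE) - 1L
  expect_equal(cut8, oracle_max_entropy_cut(counts))

  # histogram-preserving permutation leaves the threshold unchanged
  set.seed(1)
  expect_equal(max_entropy_threshold(sample(vals), n_bins = 8), thr8)
  expect_error(max_entropy_threshold(rep(5, 100)), "degenerate")
})

test_that("foci detection recovers known blobs", {
  pos <- matrix(c(-400, -300, -300,
                  400, 300, 300,
                  0, 400, -200), 3, byrow = TRUE)
  sim <- small_blob_sim(pos, noise_level = 0)
  foci <- detect_foci(sim$channels$ch1)
  expect_equal(nrow(foci), 3)
  truth <- sweep(pos, 2, sim$truth$origin_nm, `+`)
  for (i in seq_len(3)) {
    d <- sqrt(min(colSums((t(truth) -
                             unlist(foci[i, c("x_nm", "y_nm",
                                              "z_nm")]))^2)))
    expect_lt(d, 125)  # within one (axial) voxel
  }

  blank <- voxel_stack(array(0, c(6, 12, 12)))
  expect_equal(nrow(detect_foci(blank)), 0)

  # blobs closer than a voxel merge into one focus
  near <- matrix(c(0, 0, 0, 30, 0, 0), 2, byrow = TRUE)
  simn <- small_blob_sim(near, noise_level = 0)
  expect_equal(nrow(detect_foci(simn$channels$ch1)), 1)
})

test_that("foci detection is reliable across seeded replicates", {
  pos <- matrix(c(-400, -300, -300,
                  400, 300, 300,
                  -350, 350, 250,
                  300, -400, -250), 4, byrow = TRUE)
  hits <- vapply(1:10, function(s) {
    sim <- small_blob_sim(pos, seed = s, noise_level = 10,
                          intensity = 150)  # SNR > 5, separation > 2 FWHM
    nrow(detect_foci(sim$channels$ch1))
  }, 0L)
  expect_gte(mean(hits == 4), 0.95)
})

test_that("closest-foci distances match the brute-force oracle", {
  a <- data.frame(x_nm = 0, y_nm = 0, z_nm = 0)
  expect_equal(pair_border_distances(a, a), 0)
  b <- data.frame(x_nm = c(300, 1000), y_nm = 0, z_nm = 0)
  expect_equal(pair_border_distances(a, b), 300)
  expect_error(pair_border_distances(a[0, ], b), "at least one")

  set.seed(4)
  for (rep in 1:5) {
    pa <- matrix(runif(15, 0, 1000), ncol = 3,
                 dimnames = list(NULL, c("x_nm", "y_nm", "z_nm")))
    pb <- matrix(runif(21, 0, 1000), ncol = 3,
                 dimnames = list(NULL, c("x_nm", "y_nm", "z_nm")))
    expect_equal(pair_border_distances(pa, pb),
                 oracle_nearest_distances(pa, pb))
    sym <- pair_border_distances(pa, pb, symmetrize = TRUE)
    expect_length(sym, nrow(pa) + nrow(pb))
  }

  # invariance under global rotation and translation
  set.seed(5)
  pa <- matrix(runif(30, 0, 500), ncol = 3)
  pb <- matrix(runif(30, 0, 500), ncol = 3)
  theta <- 0.7
  rot <- matrix(c(cos(theta), -sin(theta), 0,
                  sin(theta), cos(theta), 0, 0, 0, 1), 3, byrow = TRUE)
  tf <- function(p) sweep(p %*% rot, 2, c(100, -50, 20), `+`)
  to_df <- function(p) setNames(as.data.frame(p),
                                c("x_nm", "y_nm", "z_nm"))
  expect_equal(pair_border_distances(to_df(tf(pa)), to_df(tf(pb))),
               pair_border_distances(to_df(pa), to_df(pb)),
               tolerance = 1e-10)
})

test_that("pairing fraction follows the binomial oracle", {
  single <- replicate(10, data.frame(channel = "ch1"), simplify = FALSE)
  pf <- pairing_fraction(single, "ch1")
  expect_equal(pf$fraction, 1)
  expect_error(pairing_fraction(list(), "ch1"), "at least one")

  sim <- generate_paired_loci_cells(10000, 1, 0.65,
                                    config = sim_config(seed = 12))
  cells <- lapply(sim$cells, function(cl)
    data.frame(channel = rep("ch1", nrow(cl$ch1))))
  pf <- pairing_fraction(cells, "ch1")
  expect_lt(abs(pf$fraction - 0.65), 3 * sqrt(0.65 * 0.35 / 10000))
  expect_equal(pf$se, sqrt(pf$fraction * (1 - pf$fraction) / 10000))
})

test_that("p(r), R_g and D_max behave as defined", {
  two <- data.frame(x_nm = c(0, 500), y_nm = 0, z_nm = 0)
  pr <- pr_distribution(two, bin_width = 100)
  expect_equal(sum(pr$p), 1)
  expect_equal(sum(pr$p > 0), 1)
  expect_equal(pr$mids[pr$p > 0], 550)  # left-closed bin [500, 600)

  set.seed(6)
  n <- 9
  cell <- data.frame(x_nm = runif(n, 0, 800), y_nm = runif(n, 0, 800),
                     z_nm = runif(n, 0, 800))
  pr2 <- pr_distribution(cell, bin_width = 50)
  expect_equal(pr2$n_pairs, n * (n - 1) / 2)
  expect_equal(sum(pr2$p), 1)
  expect_lte(pr2$D_max, max(dist(cell)) + 50)
  expect_lte(pr2$R_g, pr2$D_max)
  expect_error(pr_distribution(two[1, ]), "at least 2")

  expect_equal(radius_of_gyration(two[1, ]), 0)
  expect_equal(radius_of_gyration(two), 250)  # two foci at d -> d/2
  a <- 300
  cube <- expand.grid(x_nm = c(0, a), y_nm = c(0, a), z_nm = c(0, a))
  expect_equal(radius_of_gyration(cube), a * sqrt(3) / 2)
})

test_that("D_max interpolation follows the cumulative p(r)", {
  pr1 <- list(breaks = c(0, 100, 200), p = c(0, 1))
  expect_equal(dmax_from_pr(pr1, 0.97), 100 + 0.97 * 100)
  expect_equal(dmax_from_pr(pr1, 1), 200)

  # uniform points in a sphere: D_max at 97% matches the direct quantile
  set.seed(7)
  g <- matrix(rnorm(3 * 800), ncol = 3)
  g <- g / sqrt(rowSums(g^2)) * runif(800)^(1 / 3) * 500
  cell <- setNames(as.data.frame(g), c("x_nm", "y_nm", "z_nm"))
  pr <- pr_distribution(cell, bin_width = 20)
  oracle <- quantile(dist(g), 0.97)
  expect_lt(abs(pr$D_max - oracle), 20)
})
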