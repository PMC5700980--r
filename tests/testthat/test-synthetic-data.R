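test_that("sim_config validates physical sizes and seeds reproduce", {
  expect_error(sim_config(voxel_size_xy = -1), "positive")
  expect_error(sim_config(noise_level = -1), "noise_level")
  sim1 <- small_blob_sim(matrix(c(100, 0, 0), 1), seed = 42,
                         noise_level = 5)
  sim2 <- small_blob_sim(matrix(c(100, 0, 0), 1), seed = 42,
                         noise_level = 5)
  expect_identical(sim1$channels$ch1$intensities,
                   sim2$channels$ch1$intensities)
  expect_identical(sim1$channels$dapi$intensities,
                   sim2$channels$dapi$intensities)
})

test_that("nucleus stack renders blobs on the grid with ground truth", {
  pos <- matrix(c(100, -200, 0, 0, 300, 200, -300, 0, -100), 3,
                byrow = TRUE)
  sim <- small_blob_sim(pos, noise_level = 0)
  expect_equal(nrow(sim$truth$loci), 3)
  expect_true(all(sim$channels$ch1$intensities >= 0))

  # a locus placed exactly at a voxel center puts the argmax there
  cfg <- sim_config(seed = 1, nucleus_radii = c(800, 800, 600),
                    noise_level = 0)
  d <- sim$truth$dims
  # voxel (z=6, y=20, x=25) center, in nucleus-centered nm coordinates
  tz <- 6L; ty <- 20L; tx <- 25L
  sim2 <- generate_nucleus_stack(cfg, data.frame(
    x_nm = (tx - 0.5) * cfg$voxel_size_xy - d[3] * cfg$voxel_size_xy / 2,
    y_nm = (ty - 0.5) * cfg$voxel_size_xy - d[2] * cfg$voxel_size_xy / 2,
    z_nm = (tz - 0.5) * cfg$voxel_size_z - d[1] * cfg$voxel_size_z / 2,
    channel = 1, intensity = 50))
  am <- arrayInd(which.max(sim2$channels$ch1$intensities),
                 dim(sim2$channels$ch1$intensities))
  expect_equal(as.integer(am), c(tz, ty, tx))

  expect_error(small_blob_sim(matrix(c(5000, 0, 0), 1)),
               "outside nucleus")
})

test_that("paired loci cells honour the pairing probability", {
  cfg <- sim_config(seed = 3)
  all1 <- generate_paired_loci_cells(20, 4, 1, config = cfg)
  expect_true(all(vapply(all1$cells, function(c) nrow(c$ch1),
                         0L) == 4L))
  all0 <- generate_paired_loci_cells(20, 4, 0, config = cfg)
  expect_true(all(vapply(all0$cells, function(c) nrow(c$ch1),
                         0L) == 8L))

  # binomial oracle at p = 0.65
  n <- 10000
  sim <- generate_paired_loci_cells(n, 1, 0.65, config = cfg)
  frac <- mean(sim$truth$paired[!duplicated(
    paste(sim$truth$cell, sim$truth$locus))])
  se <- sqrt(0.65 * 0.35 / n)
  expect_lt(abs(frac - 0.65), 3 * se)

  # truncated-normal distances are non-negative with the right mean
  expect_true(all(sim$truth$distance_nm >= 0))
  expect_warning(
    generate_paired_loci_cells(5, 1, 1, c(mu = -500, sigma = 100),
                               config = cfg),
    "truncated")
})

test_that("freely jointed chain distances obey ideal-chain statistics", {
  one <- sample_polymer_distances(10, 10, 60, 10, n_chains = 50, seed = 1)
  expect_equal(one$d_nm, rep(60, 50))

  ch <- sample_polymer_distances(100, 10, 60, c(100, 400, 1000),
                                 n_chains = 500, seed = 2)
  for (L in c(10, 40, 100)) {
    d2 <- ch$d_nm[ch$d_kb == L * 10]^2
    # E[R^2] = L b^2, Var[R^2] = (2/3) L^2 b^4 for an ideal chain
    se <- sqrt(2 / 3) * L * 60^2 / sqrt(500)
    expect_lt(abs(mean(d2) - L * 60^2), 3 * se)
  }
  expect_identical(ch, sample_polymer_distances(
    100, 10, 60, c(100, 400, 1000), n_chains = 500, seed = 2))
  expect_error(sample_polymer_distances(10, 10, 60, 200, 5, 1),
               "longer than chain")
  expect_error(sample_polymer_distances(10, 10, 60, 15, 5, 1),
               "multiples")
})

test_that("storm fields place compartments and background as stated", {
  bg <- generate_storm_field(0, 200, 100, background_density = 100,
                             field_size = c(2000, 2000), seed = 5)
  lambda <- 100 * 4  # 4 um^2
  expect_lt(abs(nrow(bg$locs) - lambda), 4 * sqrt(lambda) + 1)

  disc <- generate_storm_field(1, 200, 200, background_density = 0,
                               seed = 6)
  ctr <- c(disc$truth$compartments$x_nm, disc$truth$compartments$y_nm)
  r <- sqrt((disc$locs$x_nm - ctr[1])^2 + (disc$locs$y_nm - ctr[2])^2)
  expect_true(all(r <= 100 + 1e-9))

  co <- generate_storm_field(3, 300, 300, background_density = 0,
                             two_channel_mode = "co-occurring", seed = 7)
  tr <- co$truth$compartments
  expect_identical(tr$diameter_nm[tr$channel == 1],
                   tr$diameter_nm[tr$channel == 2])
  c1 <- colMeans(co$locs[co$locs$channel == 1, c("x_nm", "y_nm")])
  c2 <- colMeans(co$locs[co$locs$channel == 2, c("x_nm", "y_nm")])
  expect_lt(max(abs(c1 - c2)), 30)  # Monte-Carlo centroid error

  seg <- generate_storm_field(3, 300, 100, background_density = 0,
                              two_channel_mode = "segregated", seed = 8)
  trs <- seg$truth$compartments
  d12 <- outer(trs$x_nm[trs$channel == 1], trs$x_nm[trs$channel == 2],
               `-`)^2 +
    outer(trs$y_nm[trs$channel == 1], trs$y_nm[trs$channel == 2], `-`)^2
  min_sep <- outer(trs$diameter_nm[trs$channel == 1],
                   trs$diameter_nm[trs$channel == 2], `+`) / 2
  expect_true(all(sqrt(d12) > min_sep))

  expect_error(generate_storm_field(2, 1500, 10, 0, seed = 1,
                                    max_retries = 50),
               "overlap")
})

test_that("chip tracks tile the genome with known domains", {
  tr <- generate_chip_track(1e6, 2e4, 5e3, 5, seed = 9)
  dom <- tr$truth$domains
  expect_true(all(dom$start < dom$end))
  expect_true(all(dom$end <= 1e6))
  expect_true(all(diff(dom$start) > 0))
  # domains and gaps partition the genome
  expect_true(all(dom$start[-1] >= dom$end[-nrow(dom)]))
  covered <- sum(dom$end - dom$start)
  expect_equal(covered + (1e6 - covered), 1e6)

  # lognormal domain sizes match analytic moments
  ml <- log(2e4); sl <- 0.5
  big <- generate_chip_track(5e7, function(n) rlnorm(n, ml, sl), 5e3,
                             5, seed = 10)
  sizes <- big$truth$domains$end - big$truth$domains$start
  sizes <- sizes[-length(sizes)]  # last domain may be truncated
  mean_an <- exp(ml + sl^2 / 2)
  sd_an <- sqrt((exp(sl^2) - 1) * exp(2 * ml + sl^2))
  expect_lt(abs(mean(sizes) - mean_an), 3 * sd_an / sqrt(length(sizes)))

  expect_error(generate_chip_track(100, 2e4, 5e3, 5, seed = 1),
               "shorter than first domain")
})

test_that("hic generator plants decay, biases and blocks as specified", {
  g <- generate_hic_matrix(50, decay_exponent = 1, bias_sd = 0,
                           noise = "none", seed = 1)
  m <- g$matrix$counts
  sep <- abs(outer(1:50, 1:50, `-`))
  for (s in c(0, 3, 17)) expect_equal(var(m[sep == s]), 0)

  gb <- generate_hic_matrix(80, bias_sd = 0.4, seed = 2)
  expect_equal(exp(mean(log(gb$truth$biases))), 1, tolerance = 1e-12)
  expect_equal(gb$matrix$counts, t(gb$matrix$counts))

  blk <- generate_hic_matrix(30, decay_exponent = 1, bias_sd = 0,
                             tad_blocks = list(list(start = 5, end = 10,
                                                    boost = 4)),
                             seed = 3)
  expect_equal(blk$matrix$counts[6, 9] / g$matrix$counts[6, 9], 4)

  # Poisson oracle: per-separation means match expectation
  gp <- generate_hic_matrix(100, decay_exponent = 0.8, bias_sd = 0,
                            noise = "poisson", scale = 5000, seed = 4)
  sep <- abs(outer(1:100, 1:100, `-`))
  up <- upper.tri(sep)
  for (s in c(1, 5, 20)) {
    e <- 5000 * (s + 1)^(-0.8)
    obs <- gp$matrix$counts[sep == s & up]  # independent draws only
    expect_lt(abs(mean(obs) - e), 3 * sqrt(e / length(obs)) + 1e-9)
  }
  expect_error(generate_hic_matrix(2), "n_bins")
  expect_error(generate_hic_matrix(10, decay_exponent = -1), "positive")
})
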