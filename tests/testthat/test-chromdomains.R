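track_of <- function(starts, ends, scores, genome = NULL) {
  tr <- data.frame(chrom = rep("chrS", length(starts)), start = starts,
                   end = ends, name = sprintf("p%d", seq_along(starts)),
                   score = scores, strand = rep(".", length(starts)))
  attr(tr, "genome_length") <- genome %||% max(ends)
  tr
}

test_that("peak resampling produces the per-bp oracle signal", {
  empty <- track_of(numeric(0), numeric(0), numeric(0), genome = 1000)
  sig <- peaks_to_signal(empty, resolution = 10, genome_length = 1000)
  expect_equal(sig$signal, rep(0, 100))

  one <- peaks_to_signal(track_of(100, 200, 5), resolution = 10,
                         genome_length = 500)
  expect_equal(one$signal[11:20], rep(5, 10))
  expect_equal(sum(one$signal), 5 * 10)

  # overlapping peaks: intensities add; per-bp oracle at 1 bp resolution
  tr <- track_of(c(50, 120), c(150, 250), c(2, 3), genome = 300)
  fine <- peaks_to_signal(tr, resolution = 1, genome_length = 300)
  oracle <- numeric(300)
  oracle[51:150] <- oracle[51:150] + 2
  oracle[121:250] <- oracle[121:250] + 3
  expect_equal(fine$signal, oracle)

  # partial bin overlap is fraction-weighted
  part <- peaks_to_signal(track_of(15, 25, 4), resolution = 10,
                          genome_length = 100)
  expect_equal(part$signal[2], 4 * 0.5)
  expect_equal(part$signal[3], 4 * 0.5)

  expect_warning(peaks_to_signal(track_of(c(100, 10), c(150, 50),
                                          c(1, 1), genome = 200)),
                 "sorting")
})

test_that("domain calling thresholds, drops and fuses as specified", {
  sig10 <- peaks_to_signal(track_of(5000, 15000, 8), resolution = 10,
                           genome_length = 30000)
  dom <- call_domains(sig10)
  expect_equal(nrow(dom), 1)
  expect_equal(dom$start, 5000)
  expect_equal(dom$end, 15000)

  # blocks separated by 500 bp fuse into one domain
  two <- peaks_to_signal(track_of(c(1000, 3500), c(3000, 6000),
                                  c(5, 5), genome = 10000),
                         resolution = 10)
  fused <- call_domains(two)
  expect_equal(nrow(fused), 1)
  expect_equal(c(fused$start, fused$end), c(1000, 6000))

  # a 2-bp blip is dropped (length must exceed 2 bp)
  blip <- peaks_to_signal(track_of(c(100, 5000), c(102, 9000),
                                   c(9, 9), genome = 10000),
                          resolution = 1)
  db <- call_domains(blip, fuse_gap = 1000)
  expect_equal(nrow(db), 1)
  expect_equal(db$start, 5000)

  # a peak at 1% of the maximum intensity survives the log threshold
  weak <- peaks_to_signal(track_of(c(1000, 20000), c(3000, 25000),
                                   c(1, 100), genome = 40000),
                          resolution = 10)
  dw <- call_domains(weak)
  expect_equal(nrow(dw), 2)

  expect_equal(nrow(call_domains(list(signal = rep(0, 100),
                                      resolution = 10,
                                      genome_length = 1000))), 0)
})

test_that("domain calling is idempotent and monotone in the threshold", {
  tr <- generate_chip_track(5e5, function(n) rlnorm(n, log(2e4), 0.4),
                            function(n) 3000 + rexp(n, 1 / 5000),
                            function(n) runif(n, 1, 10), seed = 41)
  sig <- peaks_to_signal(tr$track, resolution = 10,
                         genome_length = 5e5)
  dom <- call_domains(sig)
  # idempotence: re-rasterize the called domains and call again
  redo <- peaks_to_signal(track_of(dom$start, dom$end,
                                   rep(1, nrow(dom)), genome = 5e5),
                          resolution = 10)
  dom2 <- call_domains(redo)
  expect_equal(dom2$start, dom$start)
  expect_equal(dom2$end, dom$end)

  cov <- vapply(c(0.05, 0.1, 0.3, 0.6, 0.9), function(f)
    sum(call_domains(sig, log_threshold_frac = f)$length_bp), 0)
  expect_true(all(diff(cov) <= 0))

  # chains of sub-1-kb gaps collapse into a single domain
  chain <- peaks_to_signal(
    track_of(c(0, 1500, 3000, 4500), c(1000, 2500, 4000, 5500),
             rep(5, 4), genome = 6000), resolution = 10)
  expect_equal(nrow(call_domains(chain)), 1)
})

test_that("generator domains are recovered exactly when well separated", {
  tr <- generate_chip_track(
    1e6, function(n) 3500 + rlnorm(n, log(1.5e4), 0.4),
    function(n) 1500 + rexp(n, 1 / 4000),
    function(n) runif(n, 0.5, 10), seed = 42, peaks_per_domain = 2)
  sig <- peaks_to_signal(tr$track, resolution = 10,
                         genome_length = 1e6)
  dom <- call_domains(sig)
  tru <- tr$truth$domains
  expect_equal(nrow(dom), nrow(tru))
  expect_true(all(abs(dom$start - tru$start) <= 10))
  expect_true(all(abs(dom$end - tru$end) <= 10))
})

test_that("genomic-to-physical conversion applies the power law", {
  fit <- structure(list(prefactor = 1, exponent = 0.5),
                   class = "power_law_fit")
  dom <- data.frame(start = 0, end = 1e5, length_bp = 1e5)
  expect_equal(genomic_to_physical(dom, fit)$size_nm, 10)

  lin <- structure(list(prefactor = 7, exponent = 1),
                   class = "power_law_fit")
  dom2 <- data.frame(length_bp = c(1000, 5000, 20000))
  expect_equal(genomic_to_physical(dom2, lin)$size_nm,
               7 * dom2$length_bp / 1000)

  # batch conversion equals the per-domain scalar oracle
  fit2 <- structure(list(prefactor = 19, exponent = 0.45),
                    class = "power_law_fit")
  set.seed(43)
  dom3 <- data.frame(length_bp = round(runif(20, 3e3, 1e5)))
  batch <- genomic_to_physical(dom3, fit2)$size_nm
  oracle <- vapply(dom3$length_bp, function(L)
    19 * (L / 1000)^0.45, 0)
  expect_equal(batch, oracle)

  dom4 <- data.frame(length_bp = 1e4, state = "active")
  expect_error(genomic_to_physical(dom4, list(repressed = fit)),
               "active")
  byst <- genomic_to_physical(dom4, list(active = fit2))
  expect_equal(byst$size_nm, 19 * 10^0.45)
})

test_that("clustering percentage recovers injected clustering", {
  set.seed(44)
  pred <- rlnorm(400, log(120), 0.35)
  expect_equal(clustering_percentage(pred, pred)$percentage, 0)

  none_large <- runif(100, 10, 140)
  all_large <- runif(50, 200, 400)
  expect_equal(clustering_percentage(none_large,
                                     all_large)$percentage, 100)

  # inject extra merged compartments per cell at a known rate
  n_pred_large <- sum(pred > 150)
  cells <- lapply(1:20, function(i) {
    extra <- rlnorm(round(0.25 * n_pred_large / 0.75), log(300), 0.2)
    c(pred, extra)
  })
  cl <- clustering_percentage(pred, cells)
  expect_lt(abs(cl$percentage - 25), 10)
  expect_true(is.finite(cl$sd))

  small_obs <- list(runif(5, 10, 100))
  out <- clustering_percentage(pred, small_obs)
  expect_true(is.na(out$per_cell[1]))
})
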