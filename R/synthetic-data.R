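#' Simulation configuration
#'
#' Bundles the imaging-geometry constants used by the synthetic generators.
#' Defaults correspond to a 3D-SIM acquisition: 39.5 nm lateral and 125 nm
#' axial voxels, and point-spread-function sigmas derived from ~120 nm
#' lateral / ~300 nm axial resolution via FWHM = 2.355 sigma.
#'
#' @param seed integer seed; identical seeds reproduce identical outputs.
#' @param voxel_size_xy,voxel_size_z voxel pitch in nm.
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF sigmas in nm.
#' @param nucleus_radii ellipsoid semi-axes (x, y, z) in nm.
#' @param noise_level Gaussian camera-noise standard deviation (counts).
#' @param field_size 2D SMLM field extent (x, y) in nm.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, voxel_size_xy = 39.5, voxel_size_z = 125,
                       psf_sigma_xy = 51, psf_sigma_z = 127,
                       nucleus_radii = c(2000, 2000, 1500),
                       noise_level = 5, field_size = c(2000, 2000)) {
  assert_positive(c(voxel_size_xy, voxel_size_z, psf_sigma_xy, psf_sigma_z,
                    nucleus_radii, field_size), "physical sizes")
  if (noise_level < 0) stop("'noise_level' must be >= 0")
  structure(list(seed = as.integer(seed), voxel_size_xy = voxel_size_xy,
                 voxel_size_z = voxel_size_z, psf_sigma_xy = psf_sigma_xy,
                 psf_sigma_z = psf_sigma_z, nucleus_radii = nucleus_radii,
                 noise_level = noise_level, field_size = field_size),
            class = "sim_config")
}

# Uniform positions inside the (optionally shrunken) nucleus ellipsoid.
sample_in_ellipsoid <- function(n, radii, margin = 1) {
  g <- matrix(rnorm(3 * n), ncol = 3)
  g <- g / sqrt(rowSums(g^2))
  r <- runif(n)^(1 / 3)
  sweep(g * r, 2, radii * margin, `*`)
}

# Truncated-at-zero normal sample by rejection.
rtnorm0 <- function(n, mu, sigma) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 10, mu, sigma)
    out <- c(out, x[x >= 0])
  }
  out[seq_len(n)]
}

#' Render a multichannel 3D nucleus stack
#'
#' Builds a DAPI-like channel (smooth ellipsoidal shell plus Gaussian noise)
#' and one channel per distinct locus label, each locus rendered as an
#' anisotropic 3D Gaussian blob with the configured PSF sigmas, sampled on
#' the voxel grid.  Coordinates are in nm relative to the nucleus center.
#'
#' @param config a [sim_config()].
#' @param loci data frame with columns `x_nm`, `y_nm`, `z_nm`, `channel`,
#'   `intensity`; positions must lie inside the nucleus ellipsoid.
#' @param dapi_intensity peak DAPI intensity (counts).
#' @return List with `channels` (named list of [voxel_stack()] including
#'   `"dapi"`), `truth` (the loci table and nucleus geometry) and `config`.
#' @export
generate_nucleus_stack <- function(config, loci, dapi_intensity = 100) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(loci))
  need <- c("x_nm", "y_nm", "z_nm", "channel", "intensity")
  if (!all(need %in% names(loci)))
    stop("'loci' needs columns ", paste(need, collapse = ", "))
  rad <- config$nucleus_radii
  rn2 <- (loci$x_nm / rad[1])^2 + (loci$y_nm / rad[2])^2 +
    (loci$z_nm / rad[3])^2
  if (any(rn2 > 1))
    stop("locus outside nucleus ellipsoid (rows ",
         paste(which(rn2 > 1), collapse = ", "), ")")

  vxy <- config$voxel_size_xy; vz <- config$voxel_size_z
  nx <- ceiling(2 * rad[1] * 1.15 / vxy)
  ny <- ceiling(2 * rad[2] * 1.15 / vxy)
  nz <- ceiling(2 * rad[3] * 1.15 / vz)
  # voxel-center coordinates, origin at nucleus center
  xc <- ((seq_len(nx)) - 0.5) * vxy - nx * vxy / 2
  yc <- ((seq_len(ny)) - 0.5) * vxy - ny * vxy / 2
  zc <- ((seq_len(nz)) - 0.5) * vz - nz * vz / 2

  with_seed(config$seed, {
    # DAPI: sigmoid ellipsoidal shell
    rnorm2 <- outer(outer((zc / rad[3])^2, (yc / rad[2])^2, `+`),
                    (xc / rad[1])^2, `+`)
    dapi <- dapi_intensity / (1 + exp((sqrt(rnorm2) - 1) / 0.05))
    channels <- list(dapi = dapi)

    chan_names <- as.character(loci$channel)
    for (ch in unique(chan_names)) {
      arr <- array(0, dim = c(nz, ny, nx))
      for (i in which(chan_names == ch)) {
        sx <- config$psf_sigma_xy; sz <- config$psf_sigma_z
        ix <- which(abs(xc - loci$x_nm[i]) <= 4 * sx)
        iy <- which(abs(yc - loci$y_nm[i]) <= 4 * sx)
        iz <- which(abs(zc - loci$z_nm[i]) <= 4 * sz)
        gx <- exp(-(xc[ix] - loci$x_nm[i])^2 / (2 * sx^2))
        gy <- exp(-(yc[iy] - loci$y_nm[i])^2 / (2 * sx^2))
        gz <- exp(-(zc[iz] - loci$z_nm[i])^2 / (2 * sz^2))
        blob <- loci$intensity[i] * outer(outer(gz, gy), gx)
        arr[iz, iy, ix] <- arr[iz, iy, ix] + blob
      }
      channels[[paste0("ch", ch)]] <- arr
    }

    channels <- lapply(channels, function(a) {
      if (config$noise_level > 0)
        a <- a + array(rnorm(length(a), 0, config$noise_level), dim = dim(a))
      pmax(a, 0)
    })
    channels <- Map(function(a, nm)
      voxel_stack(a, vxy, vz, channel = nm), channels, names(channels))
    # nm offset from stack-corner origin (used by detect_foci) to the
    # nucleus-center origin in which `loci` are given
    origin <- c(x = nx * vxy / 2, y = ny * vxy / 2, z = nz * vz / 2)
    list(channels = channels,
         truth = list(loci = loci, nucleus_radii = rad,
                      dims = c(nz, ny, nx), origin_nm = origin),
         config = config)
  })
}

#' Simulate cells with paired/unpaired labeled loci
#'
#' Each of `n_loci` loci per cell is homolog-paired (a single physical copy)
#' with probability `p`, otherwise present as two copies displaced by an
#' isotropic homolog offset.  Every copy carries a channel-1 and a channel-2
#' position (the two labeled TAD borders) separated by a distance drawn from
#' a normal distribution truncated at zero.
#'
#' @param n_cells,n_loci numbers of cells and loci per cell.
#' @param pairing_prob probability `p` in \[0, 1\] that a locus is paired.
#' @param distance_model named vector `c(mu=, sigma=)`, nm; the inter-border
#'   3D distance distribution.
#' @param config a [sim_config()]; `config$seed` drives all randomness.
#' @param homolog_offset named vector `c(mean=, sd=)`, nm, for the offset
#'   between unpaired homolog copies (not constrained by the data; see
#'   vignette).
#' @return Object of class `paired_loci_sim`: `cells` (list; per cell,
#'   matrices `ch1`/`ch2` of copy positions and the `paired` flags) and
#'   `truth` (per-copy table with the drawn inter-border distances).
#' @export
generate_paired_loci_cells <- function(n_cells, n_loci, pairing_prob,
                                       distance_model = c(mu = 400,
                                                          sigma = 150),
                                       config = sim_config(),
                                       homolog_offset = c(mean = 800,
                                                          sd = 200)) {
  stopifnot(pairing_prob >= 0, pairing_prob <= 1, n_cells >= 1, n_loci >= 1)
  mu <- distance_model[["mu"]]; sigma <- distance_model[["sigma"]]
  assert_positive(sigma, "sigma")
  if (pnorm(0, mu, sigma) > 0.5)
    warning("more than half of the distance distribution is truncated at 0")

  with_seed(config$seed, {
    cells <- vector("list", n_cells)
    truth <- vector("list", n_cells)
    for (cell in seq_len(n_cells)) {
      paired <- runif(n_loci) < pairing_prob
      n_copies <- ifelse(paired, 1L, 2L)
      anchors <- sample_in_ellipsoid(n_loci, config$nucleus_radii,
                                     margin = 0.8)
      locus_id <- rep(seq_len(n_loci), n_copies)
      pos <- anchors[locus_id, , drop = FALSE]
      second <- duplicated(locus_id)
      if (any(second)) {
        off_len <- rtnorm0(sum(second), homolog_offset[["mean"]],
                           homolog_offset[["sd"]])
        dirs <- matrix(rnorm(3 * sum(second)), ncol = 3)
        dirs <- dirs / sqrt(rowSums(dirs^2))
        pos[second, ] <- pos[second, , drop = FALSE] + dirs * off_len
      }
      r <- rtnorm0(nrow(pos), mu, sigma)
      dirs2 <- matrix(rnorm(3 * nrow(pos)), ncol = 3)
      dirs2 <- dirs2 / sqrt(rowSums(dirs2^2))
      ch2 <- pos + dirs2 * r
      colnames(pos) <- colnames(ch2) <- c("x_nm", "y_nm", "z_nm")
      cells[[cell]] <- list(ch1 = pos, ch2 = ch2, paired = paired)
      truth[[cell]] <- data.frame(cell = cell, locus = locus_id,
                                  paired = paired[locus_id],
                                  distance_nm = r)
    }
    structure(list(cells = cells, truth = do.call(rbind, truth),
                   params = list(n_cells = n_cells, n_loci = n_loci,
                                 pairing_prob = pairing_prob, mu = mu,
                                 sigma = sigma)),
              class = "paired_loci_sim")
  })
}

#' Sample end-to-end distances of a freely jointed chain
#'
#' Simulates ideal (random-coil) polymer chains as 3D random walks with
#' fixed bond length and returns, for each requested subchain genomic
#' length, the end-to-end physical distances across chains.  The mean
#' squared end-to-end distance of an L-segment subchain is L * bond^2, so
#' the scaling exponent of distance vs genomic length is 1/2.
#'
#' @param n_segments segments per chain.
#' @param kb_per_segment genomic length of one segment (kb).
#' @param bond_nm fixed bond (segment) length, nm.
#' @param subchain_lengths_kb genomic lengths to probe; must be multiples of
#'   `kb_per_segment` and at most the chain length.
#' @param n_chains number of independent chains.
#' @param seed RNG seed.
#' @return Data frame with columns `d_kb`, `d_nm`, `chain`.
#' @export
sample_polymer_distances <- function(n_segments = 100, kb_per_segment = 10,
                                     bond_nm = 60, subchain_lengths_kb,
                                     n_chains = 500, seed = 1) {
  assert_positive(c(n_segments, kb_per_segment, bond_nm, n_chains),
                  "chain parameters")
  segs <- subchain_lengths_kb / kb_per_segment
  if (any(abs(segs - round(segs)) > 1e-9))
    stop("subchain lengths must be multiples of kb_per_segment")
  segs <- as.integer(round(segs))
  if (any(segs < 1) || any(segs > n_segments))
    stop("subchain longer than chain (or shorter than one segment)")

  with_seed(seed, {
    out <- vector("list", n_chains)
    for (ch in seq_len(n_chains)) {
      steps <- matrix(rnorm(3 * n_segments), ncol = 3)
      steps <- steps / sqrt(rowSums(steps^2)) * bond_nm
      pos <- apply(steps, 2, cumsum)
      if (n_segments == 1) pos <- matrix(pos, nrow = 1)
      d <- sqrt(rowSums(pos[segs, , drop = FALSE]^2))
      out[[ch]] <- data.frame(d_kb = subchain_lengths_kb, d_nm = d,
                              chain = ch)
    }
    do.call(rbind, out)
  })
}

#' Simulate an SMLM localization field with clustered compartments
#'
#' Compartments are uniform discs of drawn diameter containing a set number
#' of localizations, over a homogeneous Poisson background.  In two-channel
#' modes, channel-2 compartments are placed disjoint from channel 1
#' (`"segregated"`), at the same positions (`"co-occurring"`), or
#' independently (`"independent"`).
#'
#' @param n_compartments compartments per channel.
#' @param diameter_dist compartment diameter (nm): number, numeric vector,
#'   or function(n).
#' @param locs_per_compartment localizations per compartment: number,
#'   vector, function(n), or function(n, diameters).
#' @param background_density homogeneous background, localizations per um^2.
#' @param field_size field extent (x, y), nm.
#' @param two_channel_mode `"single"`, `"segregated"`, `"co-occurring"` or
#'   `"independent"`.
#' @param seed RNG seed.
#' @param precision_nm constant localization precision recorded per point.
#' @param max_retries placement attempts per compartment before giving up.
#' @return Object of class `storm_field`: `locs` (data frame `x_nm`, `y_nm`,
#'   `frame`, `channel`, `precision_nm`), `truth` (per-compartment centers,
#'   diameters, counts; background counts) and the field geometry.
#' @export
generate_storm_field <- function(n_compartments, diameter_dist,
                                 locs_per_compartment, background_density,
                                 field_size = c(2000, 2000),
                                 two_channel_mode = c("single", "segregated",
                                                      "co-occurring",
                                                      "independent"),
                                 seed = 1, precision_nm = 15,
                                 max_retries = 200) {
  two_channel_mode <- match.arg(two_channel_mode)
  stopifnot(n_compartments >= 0, background_density >= 0)
  w <- field_size[1]; h <- field_size[2]

  draw_diams <- as_sampler(diameter_dist, "diameter_dist")
  draw_locs <- if (is.function(locs_per_compartment) &&
                   length(formals(locs_per_compartment)) >= 2)
    locs_per_compartment
  else {
    smp <- as_sampler(locs_per_compartment, "locs_per_compartment")
    function(n, diameters) smp(n)
  }

  place_discs <- function(diams, avoid) {
    centers <- matrix(NA_real_, nrow = length(diams), ncol = 2)
    for (i in seq_along(diams)) {
      r <- diams[i] / 2
      if (2 * r >= min(w, h)) stop("compartment does not fit in field")
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        cand <- c(runif(1, r, w - r), runif(1, r, h - r))
        prev <- rbind(avoid,
                      if (i > 1) cbind(centers[seq_len(i - 1), 1:2,
                                               drop = FALSE],
                                       diams[seq_len(i - 1)]))
        if (is.null(prev) || nrow(prev) == 0 ||
            all(sqrt((prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2) >
                (prev[, 3] + diams[i]) / 2)) {
          centers[i, ] <- cand; ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place compartments without overlap after ",
                    max_retries, " retries")
    }
    centers
  }

  disc_points <- function(center, diam, n) {
    rr <- diam / 2 * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    cbind(center[1] + rr * cos(th), center[2] + rr * sin(th))
  }

  with_seed(seed, {
    channels <- if (two_channel_mode == "single") 1L else 1:2
    locs <- list(); truth_comp <- list(); n_bg <- integer(0)
    discs1 <- NULL
    for (ch in channels) {
      if (n_compartments > 0) {
        if (ch == 2 && two_channel_mode == "co-occurring") {
          diams <- truth_comp[[1]]$diameter_nm
          centers <- cbind(truth_comp[[1]]$x_nm, truth_comp[[1]]$y_nm)
        } else {
          diams <- draw_diams(n_compartments)
          assert_positive(diams, "diameters")
          avoid <- if (ch == 2 && two_channel_mode == "segregated")
            discs1 else NULL
          centers <- place_discs(diams, avoid)
        }
        counts <- round(draw_locs(n_compartments, diams))
        pts <- do.call(rbind, lapply(seq_len(n_compartments), function(i)
          disc_points(centers[i, ], diams[i], counts[i])))
      } else {
        diams <- numeric(0); centers <- matrix(0, 0, 2)
        counts <- integer(0); pts <- matrix(0, 0, 2)
      }
      if (ch == 1) discs1 <- cbind(centers, diams)
      nb <- rpois(1, background_density * w * h / 1e6)
      bg <- cbind(runif(nb, 0, w), runif(nb, 0, h))
      all_pts <- rbind(pts, bg)
      locs[[ch]] <- data.frame(
        x_nm = all_pts[, 1], y_nm = all_pts[, 2],
        frame = seq_len(nrow(all_pts)), channel = ch,
        precision_nm = precision_nm)
      truth_comp[[ch]] <- data.frame(
        channel = rep(ch, nrow(centers)),
        x_nm = centers[, 1], y_nm = centers[, 2],
        diameter_nm = diams, n_locs = counts)
      n_bg <- c(n_bg, nb)
    }
    structure(list(locs = do.call(rbind, locs),
                   truth = list(compartments = do.call(rbind, truth_comp),
                                n_background = n_bg),
                   field_size = field_size, mode = two_channel_mode),
              class = "storm_field")
  })
}

#' Simulate a ChIP peak track with alternating domains and gaps
#'
#' Tiles a genome with alternating gap/domain intervals whose sizes are
#' drawn from the given distributions; each domain is emitted as one or
#' more contiguous peaks with drawn intensities.  Coordinates are 0-based
#' half-open.
#'
#' @param genome_length_bp genome (or chromosome) length.
#' @param domain_size_dist,gap_dist,intensity_dist number, numeric vector,
#'   or function(n) samplers for domain sizes (bp), gap sizes (bp) and peak
#'   intensities.
#' @param seed RNG seed.
#' @param chrom chromosome name used in the track.
#' @param peaks_per_domain peaks tiling each domain (number or function(n)).
#' @return List with `track` (BED-like data frame `chrom`, `start`, `end`,
#'   `name`, `score`, `strand`) and `truth` (the true domain intervals).
#' @export
generate_chip_track <- function(genome_length_bp, domain_size_dist,
                                gap_dist, intensity_dist, seed = 1,
                                chrom = "chrS", peaks_per_domain = 1) {
  assert_positive(genome_length_bp, "genome_length_bp")
  d_dom <- as_sampler(domain_size_dist, "domain_size_dist")
  d_gap <- as_sampler(gap_dist, "gap_dist")
  d_int <- as_sampler(intensity_dist, "intensity_dist")
  d_k <- as_sampler(peaks_per_domain, "peaks_per_domain")

  with_seed(seed, {
    first_dom <- max(1, round(d_dom(1)))
    if (first_dom > genome_length_bp)
      stop("genome shorter than first domain")
    pos <- 0; domains <- list(); peaks <- list()
    dom_next <- first_dom
    repeat {
      gap <- max(1, round(d_gap(1)))
      pos <- min(pos + gap, genome_length_bp)
      if (pos >= genome_length_bp) break
      dlen <- if (!is.null(dom_next)) dom_next else max(1, round(d_dom(1)))
      dom_next <- NULL
      dstart <- pos
      dend <- min(pos + dlen, genome_length_bp)
      domains[[length(domains) + 1]] <- c(dstart, dend)
      k <- max(1L, as.integer(round(d_k(1))))
      cuts <- unique(round(seq(dstart, dend, length.out = k + 1)))
      for (p in seq_len(length(cuts) - 1))
        peaks[[length(peaks) + 1]] <-
          data.frame(chrom = chrom, start = cuts[p], end = cuts[p + 1],
                     name = sprintf("peak_%d", length(peaks) + 1),
                     score = d_int(1), strand = ".")
      pos <- dend
      if (pos >= genome_length_bp) break
    }
    dom_df <- if (length(domains))
      data.frame(chrom = chrom,
                 start = vapply(domains, `[`, 0, 1),
                 end = vapply(domains, `[`, 0, 2))
    else data.frame(chrom = character(0), start = numeric(0),
                    end = numeric(0))
    track <- do.call(rbind, peaks)
    attr(track, "genome_length") <- genome_length_bp
    list(track = track, truth = list(domains = dom_df,
                                     genome_length = genome_length_bp))
  })
}

#' Simulate a Hi-C contact matrix with distance decay and bin biases
#'
#' Expected counts are `scale * (|i-j|+1)^(-decay_exponent) * boost(i,j) *
#' b_i * b_j`, with multiplicative lognormal bin biases `b` normalized to
#' geometric mean 1, optional block boosts (TAD-like), and optional Poisson
#' sampling of the symmetric matrix.
#'
#' @param n_bins number of bins (>= 3).
#' @param bin_size_bp bin width.
#' @param decay_exponent distance-decay exponent (> 0).
#' @param tad_blocks list of `list(start=, end=, boost=)` bin ranges
#'   (1-based, inclusive) whose intra-block contacts are multiplied.
#' @param bias_sd standard deviation of `log(b)`.
#' @param noise `"none"` for expected counts, `"poisson"` to sample.
#' @param scale count level at distance 0.
#' @param seed RNG seed.
#' @param chrom chromosome label.
#' @return List with `matrix` (a [contact_matrix()]) and `truth` (biases,
#'   expected counts, parameters).
#' @export
generate_hic_matrix <- function(n_bins, bin_size_bp = 10000,
                                decay_exponent = 1, tad_blocks = NULL,
                                bias_sd = 0.2, noise = c("none", "poisson"),
                                scale = 100, seed = 1, chrom = "chrS") {
  noise <- match.arg(noise)
  if (n_bins < 3) stop("'n_bins' must be >= 3")
  assert_positive(decay_exponent, "decay_exponent")

  with_seed(seed, {
    sep <- abs(outer(seq_len(n_bins), seq_len(n_bins), `-`))
    expected <- scale * (sep + 1)^(-decay_exponent)
    for (blk in tad_blocks) {
      idx <- blk$start:blk$end
      expected[idx, idx] <- expected[idx, idx] * blk$boost
    }
    b <- exp(rnorm(n_bins, 0, bias_sd))
    b <- b / exp(mean(log(b)))  # geometric mean 1 by construction
    m <- expected * outer(b, b)
    if (noise == "poisson") {
      up <- upper.tri(m, diag = TRUE)
      m[up] <- rpois(sum(up), m[up])
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
    }
    bins <- data.frame(chrom = chrom,
                       start = (seq_len(n_bins) - 1) * bin_size_bp,
                       end = seq_len(n_bins) * bin_size_bp)
    list(matrix = contact_matrix(m, bin_size_bp, chrom = chrom,
                                 bins = bins),
         truth = list(biases = b, expected = expected,
                      decay_exponent = decay_exponent, scale = scale,
                      tad_blocks = tad_blocks))
  })
}
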