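#' Voxel stack container
#'
#' A 3D fluorescence intensity grid with anisotropic voxel sizes.  The
#' array is indexed `[z, y, x]`; physical coordinates are in nm with the
#' origin at the stack corner, voxel centers at `(i - 0.5) * pitch`.
#'
#' @param intensities non-negative 3D array, dim `(nz, ny, nx)`.
#' @param voxel_size_xy,voxel_size_z voxel pitch, nm.
#' @param channel channel label.
#' @return Object of class `voxel_stack`.
#' @export
voxel_stack <- function(intensities, voxel_size_xy = 39.5,
                        voxel_size_z = 125, channel = "ch1") {
  if (!is.array(intensities) || length(dim(intensities)) != 3)
    stop("'intensities' must be a 3D array (z, y, x)")
  if (any(intensities < 0)) stop("intensities must be >= 0")
  assert_positive(c(voxel_size_xy, voxel_size_z), "voxel sizes")
  structure(list(intensities = intensities, voxel_size_xy = voxel_size_xy,
                 voxel_size_z = voxel_size_z, channel = channel),
            class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<voxel_stack '%s'> %d x %d x %d voxels (z,y,x), %.1f/%.0f nm\n",
    x$channel, d[1], d[2], d[3], x$voxel_size_xy, x$voxel_size_z))
  invisible(x)
}

# Separable 3D Gaussian blur with edge replication.  sigma_vox is in voxel
# units per array dimension (z, y, x); a sigma of 0 skips that axis.
gaussian_blur_3d <- function(arr, sigma_vox) {
  blur_axis1 <- function(a, sigma) {
    if (sigma <= 0) return(a)
    half <- max(1L, ceiling(3 * sigma))
    kern <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
    kern <- kern / sum(kern)
    d <- dim(a)
    m <- matrix(a, nrow = d[1])
    padded <- rbind(m[rep(1L, half), , drop = FALSE], m,
                    m[rep(d[1], half), , drop = FALSE])
    f <- stats::filter(padded, kern, sides = 2)
    array(f[(half + 1):(half + d[1]), ], dim = d)
  }
  for (ax in 1:3) {
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
    arr <- aperm(blur_axis1(aperm(arr, perm), sigma_vox[ax]), perm)
  }
  arr
}

# Otsu's between-class-variance threshold on an intensity sample.
otsu_threshold <- function(values, n_bins = 256) {
  rng <- range(values)
  if (diff(rng) <= 0) return(NA_real_)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(values, edges,
                                       rightmost.closed = TRUE), n_bins),
                     nbins = n_bins)
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w0 <- cumsum(p)
  mu_cum <- cumsum(p * mids)
  mu_t <- mu_cum[n_bins]
  valid <- w0 > 0 & w0 < 1
  bcv <- rep(-Inf, n_bins)
  bcv[valid] <- (mu_t * w0[valid] - mu_cum[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  # plateau (e.g. two delta masses): take the middle of the maximal range
  top <- which(bcv >= max(bcv) * (1 - 1e-12))
  edges[round(mean(range(top))) + 1]
}

#' Segment the nucleus from a DAPI stack
#'
#' Applies a Gaussian low-pass filter so only large-scale (nuclear-shape)
#' information remains, computes an intensity threshold per z-plane,
#' applies the average of the per-plane thresholds to the whole 3D region,
#' and keeps the largest connected supra-threshold component.
#'
#' @param dapi a [voxel_stack()] of the DAPI channel.
#' @param roi optional xy rectangle `c(xmin, xmax, ymin, ymax)` in voxel
#'   indices; all z planes are kept.
#' @param lowpass_sigma_nm lateral low-pass Gaussian sigma, nm.
#' @param lowpass_sigma_z_nm axial low-pass sigma, nm (default 0: the
#'   filter acts within each z plane, so planes outside the nucleus stay
#'   flat and are excluded from the threshold average).
#' @param plane_method per-plane threshold rule: Otsu (default) or
#'   mean + `k_sd` standard deviations.
#' @param k_sd multiplier for the `"mean_sd"` rule.
#' @return Object of class `nucleus_mask`: logical array congruent with the
#'   (ROI-cropped) stack, nuclear volume in um^3, and the threshold used.
#' @export
segment_nucleus <- function(dapi, roi = NULL, lowpass_sigma_nm = 150,
                            lowpass_sigma_z_nm = 0,
                            plane_method = c("otsu", "mean_sd"), k_sd = 1) {
  stopifnot(inherits(dapi, "voxel_stack"))
  plane_method <- match.arg(plane_method)
  arr <- dapi$intensities
  d <- dim(arr)
  if (!is.null(roi)) {
    if (roi[1] < 1 || roi[2] > d[3] || roi[3] < 1 || roi[4] > d[2] ||
        roi[1] > roi[2] || roi[3] > roi[4])
      stop("ROI outside stack xy bounds")
    arr <- arr[, roi[3]:roi[4], roi[1]:roi[2], drop = FALSE]
    d <- dim(arr)
  }
  sig_vox <- c(lowpass_sigma_z_nm / dapi$voxel_size_z,
               lowpass_sigma_nm / dapi$voxel_size_xy,
               lowpass_sigma_nm / dapi$voxel_size_xy)
  sm <- gaussian_blur_3d(arr, sig_vox)

  thr <- vapply(seq_len(d[1]), function(z) {
    v <- sm[z, , ]
    if (diff(range(v)) <= 0) return(NA_real_)
    if (plane_method == "otsu") otsu_threshold(v)
    else mean(v) + k_sd * sd(v)
  }, numeric(1))
  thr <- thr[is.finite(thr)]
  if (length(thr) == 0) stop("no nucleus found: all planes are flat")
  # planes without nuclear signal threshold near the noise floor; drop
  # them so they do not drag down the average
  thr <- thr[thr >= 0.25 * max(thr)]
  threshold <- mean(thr)

  mask <- sm >= threshold
  fg <- which(mask)
  if (length(fg) == 0) stop("no nucleus found: no supra-threshold voxels")
  labels <- cpp_label_components(dim(mask), fg - 1L, 26L)
  keep <- labels == which.max(tabulate(labels))
  mask[] <- FALSE
  mask[fg[keep]] <- TRUE
  vol <- sum(mask) * dapi$voxel_size_xy^2 * dapi$voxel_size_z / 1e9
  structure(list(mask = mask, volume_um3 = vol, threshold = threshold,
                 voxel_size_xy = dapi$voxel_size_xy,
                 voxel_size_z = dapi$voxel_size_z),
            class = "nucleus_mask")
}

#' Kapur maximum-entropy threshold
#'
#' Builds a histogram of the intensity sample and returns the cut level
#' that maximizes the sum of the Shannon entropies of the background and
#' foreground histogram partitions.
#'
#' @param values intensity sample (at least two distinct values).
#' @param n_bins histogram bins (default 256).
#' @return The threshold value (upper edge of the chosen background bin);
#'   voxels strictly above it are foreground.
#' @export
max_entropy_threshold <- function(values, n_bins = 256) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (length(values) < 2 || diff(rng) <= 0)
    stop("degenerate histogram: need at least two distinct values")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(values, edges,
                                       rightmost.closed = TRUE), n_bins),
                     nbins = n_bins)
  p <- counts / sum(counts)
  P <- cumsum(p)
  plogp <- ifelse(p > 0, -p * log(p), 0)
  Hc <- cumsum(plogp)
  Ht <- Hc[n_bins]
  t <- seq_len(n_bins - 1)
  ok <- P[t] > 0 & P[t] < 1
  crit <- rep(-Inf, n_bins - 1)
  crit[ok] <- log(P[t[ok]]) + Hc[t[ok]] / P[t[ok]] +
    log(1 - P[t[ok]]) + (Ht - Hc[t[ok]]) / (1 - P[t[ok]])
  edges[which.max(crit) + 1]
}

#' Detect foci in a channel stack
#'
#' Binarizes in-mask voxels at the channel's maximum-entropy threshold,
#' labels connected components in 3D, and returns each component's
#' intensity-weighted center of mass with subvoxel resolution, converted to
#' nm using the anisotropic voxel sizes.
#'
#' @param stack a [voxel_stack()].
#' @param mask optional [segment_nucleus()] result (or logical array)
#'   congruent with the stack.
#' @param min_voxels components smaller than this are discarded.
#' @param connectivity 26 (default) or 6.
#' @param threshold optional fixed threshold overriding the maximum-entropy
#'   estimate.
#' @return Data frame with one row per focus: `x_nm`, `y_nm`, `z_nm`
#'   (stack-corner origin), `n_voxels`, `intensity`, `channel`.  Zero rows
#'   is a valid result.
#' @export
detect_foci <- function(stack, mask = NULL, min_voxels = 2,
                        connectivity = 26, threshold = NULL) {
  stopifnot(inherits(stack, "voxel_stack"))
  arr <- stack$intensities
  m <- if (is.null(mask)) array(TRUE, dim(arr))
  else if (inherits(mask, "nucleus_mask")) mask$mask else mask
  if (!identical(dim(m), dim(arr))) stop("mask and stack are not congruent")

  empty <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      z_nm = numeric(0), n_voxels = integer(0),
                      intensity = numeric(0), channel = character(0))
  vals <- arr[m]
  if (length(vals) < 2 || diff(range(vals)) <= 0) return(empty)
  thr <- threshold %||% max_entropy_threshold(vals)
  fg <- which(m & arr > thr)
  if (length(fg) == 0) return(empty)
  labels <- cpp_label_components(dim(arr), fg - 1L, as.integer(connectivity))
  coords <- arrayInd(fg, dim(arr))  # (z, y, x)
  w <- arr[fg]
  out <- do.call(rbind, lapply(split(seq_along(fg), labels), function(ii) {
    if (length(ii) < min_voxels) return(NULL)
    ww <- w[ii] / sum(w[ii])
    data.frame(
      x_nm = sum(ww * (coords[ii, 3] - 0.5)) * stack$voxel_size_xy,
      y_nm = sum(ww * (coords[ii, 2] - 0.5)) * stack$voxel_size_xy,
      z_nm = sum(ww * (coords[ii, 1] - 0.5)) * stack$voxel_size_z,
      n_voxels = length(ii), intensity = sum(w[ii]))
  }))
  if (is.null(out)) return(empty)
  out$channel <- stack$channel
  rownames(out) <- NULL
  out
}

#' Closest-focus distances between two channels
#'
#' For each focus in channel A, the Euclidean 3D distance (nm) to the
#' nearest channel-B focus — the per-cell distance between two labeled TAD
#' borders imaged in different emission channels.
#'
#' @param foci_a,foci_b data frames (or matrices) with `x_nm`, `y_nm`,
#'   `z_nm`; both non-empty.
#' @param symmetrize also include B-to-nearest-A distances.
#' @return Numeric vector of distances in nm.
#' @export
pair_border_distances <- function(foci_a, foci_b, symmetrize = FALSE) {
  pa <- as.matrix(as.data.frame(foci_a)[, c("x_nm", "y_nm", "z_nm")])
  pb <- as.matrix(as.data.frame(foci_b)[, c("x_nm", "y_nm", "z_nm")])
  if (nrow(pa) == 0 || nrow(pb) == 0)
    stop("both channels must contain at least one focus")
  nearest <- function(p, q) {
    vapply(seq_len(nrow(p)), function(i)
      sqrt(min(colSums((t(q) - p[i, ])^2))), numeric(1))
  }
  d <- nearest(pa, pb)
  if (symmetrize) d <- c(d, nearest(pb, pa))
  d
}

#' Fraction of cells with a single focus
#'
#' The homolog-pairing readout: the fraction of cells showing exactly one
#' focus in the given channel, with its binomial standard error.
#'
#' @param cells list of per-cell foci tables (as from [detect_foci()]).
#' @param channel channel label to count.
#' @return List with `fraction`, `se`, and `n` cells.
#' @export
pairing_fraction <- function(cells, channel) {
  if (length(cells) == 0) stop("need at least one cell")
  single <- vapply(cells, function(f)
    sum(f$channel == channel) == 1L, logical(1))
  f <- mean(single)
  list(fraction = f, se = sqrt(f * (1 - f) / length(cells)),
       n = length(cells))
}

#' Pairwise distance distribution p(r)
#'
#' Histogram of all pairwise 3D distances between foci, normalized to sum
#' to 1.  For a list of cells, per-cell distributions are computed on
#' shared bins and averaged (population p(r)).
#'
#' @param foci positions of one cell (matrix/data frame with `x_nm`,
#'   `y_nm`, `z_nm`), or a list of such per-cell tables.
#' @param bin_width histogram bin width, nm.
#' @param dmax_fraction area fraction defining `D_max` (default 0.97).
#' @return Object of class `pr_distribution`: `breaks`, `mids`, `p`
#'   (summing to 1), `n_pairs`, `n_cells`, plus summary `R_g` (mean
#'   per-cell radius of gyration) and `D_max`.
#' @export
pr_distribution <- function(foci, bin_width = 100, dmax_fraction = 0.97) {
  cells <- if (is.data.frame(foci) || is.matrix(foci)) list(foci) else foci
  pos <- lapply(cells, function(f) {
    p <- as.matrix(as.data.frame(f)[, c("x_nm", "y_nm", "z_nm")])
    if (nrow(p) < 2) stop("p(r) needs at least 2 foci per cell")
    p
  })
  dists <- lapply(pos, function(p) as.numeric(dist(p)))
  top <- max(unlist(dists))
  breaks <- seq(0, (floor(top / bin_width) + 1) * bin_width, by = bin_width)
  per_cell <- vapply(dists, function(d) {
    h <- tabulate(pmin(findInterval(d, breaks, rightmost.closed = TRUE),
                       length(breaks) - 1), nbins = length(breaks) - 1)
    h / sum(h)
  }, numeric(length(breaks) - 1))
  p <- if (is.matrix(per_cell)) rowMeans(per_cell) else per_cell
  rg <- mean(vapply(pos, radius_of_gyration, numeric(1)))
  out <- structure(list(breaks = breaks,
                        mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                        p = p, n_pairs = sum(lengths(dists)),
                        n_cells = length(cells), R_g = rg,
                        dmax_fraction = dmax_fraction),
                   class = "pr_distribution")
  out$D_max <- dmax_from_pr(out, dmax_fraction)
  out
}

#' Radius of gyration of a focus set
#'
#' Root-mean-square distance of focus centers from their centroid
#' (unweighted).
#'
#' @param foci matrix or data frame with `x_nm`, `y_nm`, `z_nm`.
#' @return `R_g` in nm.
#' @export
radius_of_gyration <- function(foci) {
  p <- as.matrix(as.data.frame(foci)[, c("x_nm", "y_nm", "z_nm")])
  if (nrow(p) == 0) stop("need at least one focus")
  ctr <- colMeans(p)
  sqrt(mean(rowSums(sweep(p, 2, ctr)^2)))
}

#' Maximum extent D_max from a p(r) distribution
#'
#' The smallest distance at which the cumulative area under p(r) reaches
#' `fraction` (default 97%), with linear interpolation inside the crossing
#' bin.
#'
#' @param pr a [pr_distribution()] or a list with `breaks` and `p`.
#' @param fraction cumulative-area fraction in (0, 1\].
#' @return `D_max` in nm.
#' @export
dmax_from_pr <- function(pr, fraction = 0.97) {
  stopifnot(fraction > 0, fraction <= 1)
  p <- pr$p / sum(pr$p)
  cum <- cumsum(p)
  idx <- which(cum >= fraction - 1e-12)[1]
  prev <- if (idx > 1) cum[idx - 1] else 0
  width <- pr$breaks[idx + 1] - pr$breaks[idx]
  pr$breaks[idx] + (fraction - prev) / p[idx] * width
}
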