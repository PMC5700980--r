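loc_coords <- function(locs) {
  df <- as.data.frame(locs)
  if (!all(c("x_nm", "y_nm") %in% names(df)))
    stop("localization table needs columns x_nm, y_nm")
  as.matrix(df[, c("x_nm", "y_nm")])
}

#' Coordinate-based colocalization (CBC)
#'
#' For every channel-A localization, the neighbor-density gradients
#' `D_AA(r)` and `D_AB(r)` (counts within radius r, normalized by r^2 and
#' anchored at `Rmax`) are computed over a schedule of radii; the
#' colocalization value is the Spearman rank correlation of the two
#' gradients, weighted by `exp(-E_AB / Rmax)` where `E_AB` is the distance
#' to the nearest B localization.  `CA` is in \[-1, 1\]: ~1 for perfectly
#' correlated (co-occurring) channels, ~0 for independent, < 0 for
#' anti-correlated (segregated) distributions.
#'
#' A channel-B point exactly coincident with the A point under evaluation
#' is treated as the same molecule: it is excluded from the B-count
#' gradient but still yields `E_AB = 0`.
#'
#' @param locs_a,locs_b localization tables with `x_nm`, `y_nm`.
#' @param radii increasing radii schedule, nm (>= 2 values).
#' @param rmax maximum search radius, nm (defaults to `max(radii)`).
#' @return Object of class `cbc_result`: per-A-localization `ca` values,
#'   the radii, `rmax`, and `n_no_neighbors` (points with no neighbors at
#'   `rmax`, whose CA is defined as 0).
#' @export
cbc <- function(locs_a, locs_b, radii = seq(10, 300, by = 10),
                rmax = max(radii)) {
  a <- loc_coords(locs_a); b <- loc_coords(locs_b)
  if (nrow(a) == 0 || nrow(b) == 0) stop("both channels must be non-empty")
  if (length(radii) < 2) stop("need at least 2 radii")
  radii <- sort(radii)
  if (max(radii) > rmax) stop("radii must not exceed rmax")

  aa <- cpp_radial_counts(a[, 1], a[, 2], a[, 1], a[, 2], radii, TRUE)
  ab <- cpp_radial_counts(a[, 1], a[, 2], b[, 1], b[, 2], radii, FALSE)
  n_aa <- aa$counts
  n_ab <- ab$counts - as.integer(ab$nearest == 0)  # drop self-coincidence
  nr <- length(radii)
  r2 <- radii^2

  ca <- numeric(nrow(a))
  no_nb <- 0L
  for (i in seq_len(nrow(a))) {
    if (n_aa[i, nr] == 0 || n_ab[i, nr] == 0) {
      ca[i] <- 0; no_nb <- no_nb + 1L
      next
    }
    d_aa <- n_aa[i, ] / r2 * rmax^2 / n_aa[i, nr]
    d_ab <- n_ab[i, ] / r2 * rmax^2 / n_ab[i, nr]
    if (sd(d_aa) == 0 && sd(d_ab) == 0) rho <- 1
    else if (sd(d_aa) == 0 || sd(d_ab) == 0) rho <- 0
    else rho <- suppressWarnings(cor(d_aa, d_ab, method = "spearman"))
    if (!is.finite(rho)) rho <- 0
    ca[i] <- rho * exp(-ab$nearest[i] / rmax)
  }
  structure(list(ca = ca, radii = radii, rmax = rmax,
                 n_no_neighbors = no_nb),
            class = "cbc_result")
}

#' Fraction of co-occurring localizations
#'
#' @param x a [cbc()] result or a numeric vector of CA values.
#' @param threshold CA cutoff (default 0.5).
#' @return Fraction of localizations with `CA > threshold`.
#' @export
co_occurrence_fraction <- function(x, threshold = 0.5) {
  ca <- if (inherits(x, "cbc_result")) x$ca else x
  if (length(ca) == 0) stop("need at least one CA value")
  mean(ca > threshold)
}

#' Voronoi segmentation of SMLM compartments
#'
#' Converts the localization field into a bounded Voronoi diagram (one
#' polygon per localization; local density = inverse polygon area),
#' thresholds densities at `density_factor` times the average density
#' `N / field area`, merges supra-threshold polygons that touch, and keeps
#' merged groups of at least `min_polygons` polygons as compartments.  By
#' default the thresholded density of a polygon is smoothed over its
#' first-rank neighbors, which makes a spatially random field yield no
#' segmented compartment (the calibration null).
#'
#' @param locs localization table with `x_nm`, `y_nm` (>= 4 points).
#' @param bounds field rectangle `c(xmin, xmax, ymin, ymax)` nm; boundary
#'   polygons are clipped to it.  Default: the point range.
#' @param density_factor threshold multiplier on the average density.
#' @param min_polygons minimum merged polygons per compartment.
#' @param smooth_rank1 smooth each polygon's density over itself and its
#'   first-rank neighbors before thresholding.
#' @return List of class `compartment_set`; each element (class
#'   `compartment`) has `members`, `area_nm2`, `n_locs`, `density`
#'   (locs/nm^2), `centroid`, `diameter_nm` (5-nm-grid equivalent
#'   diameter), and the member polygons.
#' @export
voronoi_segment <- function(locs, bounds = NULL, density_factor = 2.5,
                            min_polygons = 12, smooth_rank1 = TRUE) {
  pts <- loc_coords(locs)
  if (nrow(pts) < 4) stop("need at least 4 localizations")
  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("degenerate collinear input: localizations span no area")
  if (is.null(bounds))
    bounds <- c(range(pts[, 1]), range(pts[, 2]))[c(1, 2, 3, 4)]
  dup <- duplicated(pts)
  if (any(dup))  # deterministic sub-nm jitter so cells stay well defined
    pts[dup, ] <- pts[dup, ] + (which(dup) %% 7 + 1) * 1e-6

  vor <- cpp_voronoi(pts[, 1], pts[, 2], bounds[1], bounds[2], bounds[3],
                     bounds[4])
  area <- pmax(vor$area, 1e-12)
  field_area <- (bounds[2] - bounds[1]) * (bounds[4] - bounds[3])
  mean_density <- nrow(pts) / field_area

  dens <- if (smooth_rank1) {
    vapply(seq_len(nrow(pts)), function(i) {
      nb <- vor$neighbors[[i]]
      (1 + length(nb)) / (area[i] + sum(area[nb]))
    }, numeric(1))
  } else 1 / area
  active <- dens > density_factor * mean_density

  # union-find over touching supra-threshold polygons
  parent <- seq_len(nrow(pts))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in which(active)) {
    for (j in vor$neighbors[[i]]) {
      if (j > i && active[j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(which(active), find, integer(1))
  groups <- split(which(active), roots)
  groups <- groups[lengths(groups) >= min_polygons]

  comps <- lapply(groups, function(members) {
    comp <- structure(list(
      members = members,
      area_nm2 = sum(area[members]),
      n_locs = length(members),
      density = length(members) / sum(area[members]),
      centroid = colMeans(pts[members, , drop = FALSE]),
      polygons = vor$polygons[members]), class = "compartment")
    comp$diameter_nm <- equivalent_diameter(comp)
    comp
  })
  names(comps) <- NULL
  structure(comps, class = "compartment_set",
            threshold = density_factor * mean_density,
            mean_density = mean_density, n_locs = nrow(pts))
}

#' Summary table of segmented compartments
#'
#' @param comps a [voronoi_segment()] result.
#' @return Data frame with one row per compartment.
#' @export
compartment_table <- function(comps) {
  if (length(comps) == 0)
    return(data.frame(area_nm2 = numeric(0), n_locs = integer(0),
                      density = numeric(0), diameter_nm = numeric(0),
                      centroid_x = numeric(0), centroid_y = numeric(0)))
  do.call(rbind, lapply(comps, function(cp)
    data.frame(area_nm2 = cp$area_nm2, n_locs = cp$n_locs,
               density = cp$density, diameter_nm = cp$diameter_nm,
               centroid_x = cp$centroid[1], centroid_y = cp$centroid[2])))
}

# Rasterize a set of convex polygons onto a grid; returns a logical matrix
# plus its x/y pixel-center coordinates.
rasterize_polygons <- function(polygons, grid) {
  allv <- do.call(rbind, polygons)
  xr <- range(allv[, 1]); yr <- range(allv[, 2])
  xs <- seq(xr[1] + grid / 2, xr[2], by = grid)
  ys <- seq(yr[1] + grid / 2, yr[2], by = grid)
  if (length(xs) == 0) xs <- mean(xr)
  if (length(ys) == 0) ys <- mean(yr)
  mask <- matrix(FALSE, nrow = length(ys), ncol = length(xs))
  for (pg in polygons) {
    nv <- nrow(pg)
    if (nv < 3) next
    ix <- which(xs >= min(pg[, 1]) - grid & xs <= max(pg[, 1]) + grid)
    iy <- which(ys >= min(pg[, 2]) - grid & ys <= max(pg[, 2]) + grid)
    if (!length(ix) || !length(iy)) next
    px <- rep(xs[ix], each = length(iy))
    py <- rep(ys[iy], times = length(ix))
    inside <- rep(TRUE, length(px))
    # convex polygon: consistent cross-product sign against every edge
    sgn <- 0
    for (k in seq_len(nv)) {
      k2 <- if (k == nv) 1L else k + 1L
      ex <- pg[k2, 1] - pg[k, 1]; ey <- pg[k2, 2] - pg[k, 2]
      cr <- ex * (py - pg[k, 2]) - ey * (px - pg[k, 1])
      if (sgn == 0) {
        s <- sign(sum(sign(cr)))
        if (s != 0) sgn <- s
      }
      inside <- inside & (sgn * cr >= -1e-9)
    }
    mask[cbind(match(py[inside], ys), match(px[inside], xs))] <- TRUE
  }
  list(mask = mask, xs = xs, ys = ys)
}

#' Equivalent diameter of a compartment
#'
#' Rasterizes the merged compartment outline on a regular grid (default
#' 5 nm), fills interior holes, and returns the diameter of the circle of
#' equal area: `2 * sqrt(area / pi)`.
#'
#' @param compartment a `compartment` from [voronoi_segment()].
#' @param grid raster pitch, nm.
#' @return Equivalent diameter, nm.
#' @export
equivalent_diameter <- function(compartment, grid = 5) {
  ras <- rasterize_polygons(compartment$polygons, grid)
  mask <- ras$mask
  # fill holes: background components not touching the raster border
  bg <- which(!mask)
  if (length(bg)) {
    d <- dim(mask)
    labels <- cpp_label_components(c(d[1], d[2], 1L), bg - 1L, 6L)
    coords <- arrayInd(bg, d)
    border <- coords[, 1] == 1 | coords[, 1] == d[1] |
      coords[, 2] == 1 | coords[, 2] == d[2]
    outside <- unique(labels[border])
    mask[bg[!(labels %in% outside)]] <- TRUE
  }
  2 * sqrt(sum(mask) * grid^2 / pi)
}

#' Probability density histogram of compartment sizes
#'
#' Density-normalized histogram: the area of each bar is the relative
#' number of observations, so the bar areas sum to 1.
#'
#' @param diameters compartment diameters, nm (>= 1 value).
#' @param bin_width histogram bin width, nm.
#' @return Object of class `size_pdf`: `breaks`, `mids`, `density`.
#' @export
size_pdf <- function(diameters, bin_width = 25) {
  diameters <- diameters[is.finite(diameters)]
  if (length(diameters) == 0) stop("need at least one diameter")
  top <- (floor(max(diameters) / bin_width) + 1) * bin_width
  breaks <- seq(0, top, by = bin_width)
  counts <- tabulate(pmin(findInterval(diameters, breaks,
                                       rightmost.closed = TRUE),
                          length(breaks) - 1),
                     nbins = length(breaks) - 1)
  structure(list(breaks = breaks,
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 density = counts / (length(diameters) * bin_width)),
            class = "size_pdf")
}

render_image <- function(pts, bounds, pixel_nm) {
  nx <- max(1L, ceiling((bounds[2] - bounds[1]) / pixel_nm))
  ny <- max(1L, ceiling((bounds[4] - bounds[3]) / pixel_nm))
  ix <- pmin(pmax(ceiling((pts[, 1] - bounds[1]) / pixel_nm), 1L), nx)
  iy <- pmin(pmax(ceiling((pts[, 2] - bounds[3]) / pixel_nm), 1L), ny)
  img <- matrix(0, nrow = ny, ncol = nx)
  tab <- table(factor(iy + (ix - 1) * ny, levels = seq_len(nx * ny)))
  img[] <- as.numeric(tab)
  img
}

#' Pixel-based colocalization controls
#'
#' Renders each channel as a 2D localization-count image at the given
#' pixel size, blurs it by the median localization precision, and reports
#' the Pearson correlation over all pixels plus Manders overlap
#' coefficients.  `M1` is the fraction of channel-A intensity in pixels
#' occupied by channel B (and vice versa for `M2`); masks are taken on the
#' unblurred count images, either as any-signal (`"positive"`, default) or
#' Otsu-thresholded.
#'
#' @param locs_a,locs_b localization tables with `x_nm`, `y_nm` and
#'   optionally `precision_nm`.
#' @param pixel_nm rendering pixel size.
#' @param bounds field rectangle `c(xmin, xmax, ymin, ymax)`; default: the
#'   joint point range.
#' @param mask_method `"positive"` or `"otsu"`.
#' @return List with `pearson`, `m1`, `m2`.
#' @export
render_and_correlate <- function(locs_a, locs_b, pixel_nm = 20,
                                 bounds = NULL,
                                 mask_method = c("positive", "otsu")) {
  mask_method <- match.arg(mask_method)
  a <- loc_coords(locs_a); b <- loc_coords(locs_b)
  if (nrow(a) == 0 || nrow(b) == 0) stop("both channels must be non-empty")
  if (is.null(bounds)) {
    allp <- rbind(a, b)
    bounds <- c(range(allp[, 1]), range(allp[, 2]))
  }
  img_a <- render_image(a, bounds, pixel_nm)
  img_b <- render_image(b, bounds, pixel_nm)

  prec <- function(locs) {
    df <- as.data.frame(locs)
    if ("precision_nm" %in% names(df)) median(df$precision_nm) else 0
  }
  blur2d <- function(img, sigma_px) {
    if (sigma_px <= 0) return(img)
    arr <- array(img, dim = c(1, nrow(img), ncol(img)))
    gaussian_blur_3d(arr, c(0, sigma_px, sigma_px))[1, , ]
  }
  sm_a <- blur2d(img_a, prec(locs_a) / pixel_nm)
  sm_b <- blur2d(img_b, prec(locs_b) / pixel_nm)

  pearson <- cor(as.vector(sm_a), as.vector(sm_b))
  mask_of <- function(img) {
    if (mask_method == "positive") return(img > 0)
    thr <- otsu_threshold(as.vector(img))
    if (is.na(thr)) img > 0 else img > thr
  }
  ma <- mask_of(img_a); mb <- mask_of(img_b)
  list(pearson = pearson,
       m1 = sum(img_a[mb]) / sum(img_a),
       m2 = sum(img_b[ma]) / sum(img_b))
}
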