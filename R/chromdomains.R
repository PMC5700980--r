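#' Resample ChIP peaks into a continuous genomic signal
#'
#' Converts a peak track (0-based half-open intervals with intensities)
#' into a binned continuous signal along the genome: each bin receives the
#' sum of overlapping peak intensities, weighted by the overlapped
#' fraction of the bin.
#'
#' @param track BED-like data frame with `start`, `end`, `score`
#'   (intensity); unsorted or overlapping peaks are handled (intensities
#'   add in overlaps).
#' @param resolution bin width, bp (default 10).
#' @param genome_length genome length, bp; default: the track's
#'   `genome_length` attribute or the last peak end.
#' @return Object of class `genomic_signal`: `signal` (per-bin), the
#'   `resolution` and `genome_length`.
#' @export
peaks_to_signal <- function(track, resolution = 10, genome_length = NULL) {
  stopifnot(all(c("start", "end") %in% names(track)))
  score <- track$score %||% rep(1, nrow(track))
  genome_length <- genome_length %||% attr(track, "genome_length") %||%
    max(track$end)
  if (is.unsorted(track$start)) {
    warning("peaks not sorted by start; sorting internally")
    o <- order(track$start)
    track <- track[o, ]; score <- score[o]
  }
  n_bins <- ceiling(genome_length / resolution)
  signal <- numeric(n_bins)
  for (i in seq_len(nrow(track))) {
    s <- track$start[i]; e <- min(track$end[i], genome_length)
    if (e <= s) next
    b0 <- floor(s / resolution) + 1       # first bin touched (1-based)
    b1 <- ceiling(e / resolution)         # last bin touched
    if (b0 == b1) {
      signal[b0] <- signal[b0] + score[i] * (e - s) / resolution
    } else {
      frac0 <- (b0 * resolution - s) / resolution
      frac1 <- (e - (b1 - 1) * resolution) / resolution
      signal[b0] <- signal[b0] + score[i] * frac0
      signal[b1] <- signal[b1] + score[i] * frac1
      if (b1 - b0 > 1) {
        mid <- (b0 + 1):(b1 - 1)
        signal[mid] <- signal[mid] + score[i]
      }
    }
  }
  structure(list(signal = signal, resolution = resolution,
                 genome_length = genome_length), class = "genomic_signal")
}

#' Call genomic domains from a continuous signal
#'
#' Log-compresses the signal (`log(signal + 1)`), thresholds at
#' `log_threshold_frac` of the log-maximum (so even peaks of very low
#' intensity are retained), takes maximal supra-threshold runs as
#' candidate domains, drops segments of `min_len` bp or shorter, and fuses
#' domains separated by less than `fuse_gap` bp.
#'
#' @param signal a [peaks_to_signal()] result (or a list with `signal`,
#'   `resolution`).
#' @param log_threshold_frac fraction of the log-maximum (default 0.1).
#' @param min_len domains must extend for more than this many bp
#'   (default 2, exclusive).
#' @param fuse_gap fuse domains closer than this many bp (default 1000).
#' @return Object of class `domain_set`: data frame with `start`, `end`,
#'   `length_bp` (0-based half-open).  An all-zero signal yields an empty
#'   set.
#' @export
call_domains <- function(signal, log_threshold_frac = 0.1, min_len = 2,
                         fuse_gap = 1000) {
  s <- signal$signal
  res <- signal$resolution
  if (any(s < 0)) stop("signal must be non-negative")
  empty <- structure(
    data.frame(start = numeric(0), end = numeric(0),
               length_bp = numeric(0)), class = c("domain_set",
                                                  "data.frame"))
  if (all(s == 0)) return(empty)
  ls <- log1p(s)
  keep <- ls > log_threshold_frac * max(ls)
  r <- rle(keep)
  ends_bin <- cumsum(r$lengths)
  starts_bin <- ends_bin - r$lengths + 1
  runs <- which(r$values)
  if (!length(runs)) return(empty)
  dom <- data.frame(start = (starts_bin[runs] - 1) * res,
                    end = pmin(ends_bin[runs] * res,
                               signal$genome_length %||%
                                 (length(s) * res)))
  dom <- dom[dom$end - dom$start > min_len, , drop = FALSE]
  if (!nrow(dom)) return(empty)
  # fuse domains whose gap is < fuse_gap (order-independent, transitive)
  fused <- dom[1, , drop = FALSE]
  if (nrow(dom) > 1) {
    for (i in 2:nrow(dom)) {
      k <- nrow(fused)
      if (dom$start[i] - fused$end[k] < fuse_gap)
        fused$end[k] <- max(fused$end[k], dom$end[i])
      else fused <- rbind(fused, dom[i, ])
    }
  }
  fused$length_bp <- fused$end - fused$start
  rownames(fused) <- NULL
  structure(fused, class = c("domain_set", "data.frame"))
}

#' Predict physical domain sizes from genomic lengths
#'
#' Converts each domain's genomic length into a physical size in nm using
#' the empirical power law `size_nm = A * (length_kb)^beta` fitted from
#' imaging data ([scaling_exponent()]); the fit used can depend on the
#' domain's chromatin state.
#'
#' @param domains a [call_domains()] result (data frame with `length_bp`,
#'   optionally a `state` column).
#' @param fit a single [fit_power_law()] result, or a named list of fits
#'   keyed by chromatin state.
#' @return The domain set with an added `size_nm` column.
#' @export
genomic_to_physical <- function(domains, fit) {
  pick <- function(state) {
    if (inherits(fit, "power_law_fit")) return(fit)
    f <- fit[[state]]
    if (is.null(f)) stop("no power-law fit for chromatin state '", state,
                         "'")
    f
  }
  states <- domains$state %||% rep(NA_character_, nrow(domains))
  domains$size_nm <- vapply(seq_len(nrow(domains)), function(i) {
    f <- if (is.na(states[i])) pick(NULL) %||% fit else pick(states[i])
    if (!inherits(f, "power_law_fit")) stop("'fit' must be a power_law_fit")
    if (f$prefactor <= 0) stop("power-law prefactor must be > 0")
    f$prefactor * (domains$length_bp[i] / 1000)^f$exponent
  }, numeric(1))
  domains
}

#' Percentage of clustered compartments
#'
#' Compares the number of large (> `cutoff` nm) compartments predicted
#' from genomic epigenetic domains with the number observed per cell by
#' imaging.  With `N_pred` the per-cell expected count of predicted sizes
#' above the cutoff and `N_obs` the per-cell observed count, the clustered
#' percentage is `max(0, 1 - N_pred / N_obs) * 100`: the share of large
#' imaged compartments not accounted for by the genomic domain
#' distribution, attributed to clustering of smaller domains.
#'
#' @param predicted_nm predicted physical sizes (one genome-wide set), nm.
#' @param observed_nm observed compartment diameters: a list with one
#'   vector per cell, or a single vector (treated as one cell).
#' @param cutoff size cutoff, nm (default 150).
#' @param pred_per_cell_factor calibration factor scaling the predicted
#'   count to a per-cell expectation (imaged nuclear area / genome
#'   fraction imaged).
#' @return List with `percentage` (mean over cells), `sd`, `per_cell`,
#'   and the counts.  Cells with no observed compartment above the cutoff
#'   are reported as `NA`.
#' @export
clustering_percentage <- function(predicted_nm, observed_nm, cutoff = 150,
                                  pred_per_cell_factor = 1) {
  if (length(predicted_nm) == 0) stop("no predicted sizes")
  cells <- if (is.list(observed_nm)) observed_nm else list(observed_nm)
  if (any(lengths(cells) == 0)) stop("empty observed sample")
  n_pred <- sum(predicted_nm > cutoff) * pred_per_cell_factor
  per_cell <- vapply(cells, function(obs) {
    n_obs <- sum(obs > cutoff)
    if (n_obs == 0) return(NA_real_)
    max(0, 1 - n_pred / n_obs) * 100
  }, numeric(1))
  ok <- !is.na(per_cell)
  list(percentage = mean(per_cell[ok]),
       sd = if (sum(ok) > 1) sd(per_cell[ok]) else NA_real_,
       per_cell = per_cell, n_pred = n_pred,
       n_cells_missing = sum(!ok))
}
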