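#' Dense Hi-C contact matrix
#'
#' A square symmetric matrix of (raw or normalized) contact counts for one
#' chromosome, with its bin table and a valid-bin mask.  Matrices with
#' relative asymmetry below 1% are symmetrized by averaging; larger
#' asymmetry is an error.
#'
#' @param counts square numeric matrix, entries >= 0.
#' @param bin_size bin width, bp.
#' @param chrom chromosome label.
#' @param bins optional BED-like bin table (`chrom`, `start`, `end`); one
#'   row per bin.
#' @param mask optional logical valid-bin mask (default: all valid).
#' @return Object of class `contact_matrix`.
#' @export
contact_matrix <- function(counts, bin_size, chrom = "chr", bins = NULL,
                           mask = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("matrix must be square")
  if (any(!is.finite(counts)))
    stop("non-finite entries at positions ",
         paste(head(which(!is.finite(counts))), collapse = ", "))
  if (any(counts < 0)) stop("counts must be >= 0")
  asym <- max(abs(counts - t(counts)))
  rel <- asym / max(max(abs(counts)), .Machine$double.eps)
  if (rel > 0.01)
    stop(sprintf("matrix asymmetry %.3g exceeds 1%%", rel))
  if (asym > 0) counts <- (counts + t(counts)) / 2
  n <- nrow(counts)
  if (is.null(bins))
    bins <- data.frame(chrom = chrom, start = (seq_len(n) - 1) * bin_size,
                       end = seq_len(n) * bin_size)
  if (nrow(bins) != n) stop("bin table has ", nrow(bins),
                            " rows for ", n, " bins")
  mask <- mask %||% rep(TRUE, n)
  if (length(mask) != n) stop("mask length must equal the number of bins")
  structure(list(counts = counts, bin_size = bin_size, chrom = chrom,
                 bins = bins, mask = mask), class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins x %d bp (%d valid)\n",
              x$chrom, nrow(x$counts), x$bin_size, sum(x$mask)))
  invisible(x)
}

#' Read / write a dense contact matrix
#'
#' The on-disk format is a whitespace-delimited dense n x n text matrix
#' plus a BED3 bin table with n rows.
#'
#' @param path matrix file.
#' @param bins_path BED3 bin-table file.
#' @return A [contact_matrix()].
#' @export
read_matrix <- function(path, bins_path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  if (!file.exists(bins_path)) stop("bin table not found: ", bins_path)
  m <- as.matrix(read.table(path, header = FALSE))
  dimnames(m) <- NULL
  bins <- read.table(bins_path, header = FALSE,
                     col.names = c("chrom", "start", "end"))
  if (nrow(bins) != nrow(m))
    stop("dimension mismatch: ", nrow(m), " matrix rows vs ",
         nrow(bins), " bins")
  bin_size <- if (nrow(bins) > 0) bins$end[1] - bins$start[1] else 1
  contact_matrix(m, bin_size = bin_size, chrom = bins$chrom[1],
                 bins = bins)
}

#' @rdname read_matrix
#' @param mat a [contact_matrix()].
#' @export
write_matrix <- function(mat, path, bins_path) {
  stopifnot(inherits(mat, "contact_matrix"))
  write.table(format(mat$counts, scientific = FALSE, trim = TRUE),
              path, row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  write.table(mat$bins[, c("chrom", "start", "end")], bins_path,
              row.names = FALSE, col.names = FALSE, quote = FALSE,
              sep = "\t")
  invisible(mat)
}

#' Mask low-coverage bins
#'
#' Marks as invalid any bin whose marginal (row sum over valid columns) is
#' zero or falls below the given percentile of the nonzero marginals;
#' masked bins are excluded from all downstream computations.
#'
#' @param mat a [contact_matrix()].
#' @param percentile cutoff quantile of the nonzero marginals
#'   (default 0.02).
#' @return The matrix with an updated mask.
#' @export
filter_low_bins <- function(mat, percentile = 0.02) {
  stopifnot(inherits(mat, "contact_matrix"))
  marg <- rowSums(mat$counts)
  nz <- marg[marg > 0]
  # type-1 (inverse-ECDF) quantile: the cutoff is an observed marginal,
  # so a detached low-coverage group is masked in its entirety
  cutoff <- if (length(nz)) quantile(nz, percentile, type = 1) else Inf
  bad <- marg == 0 | marg < cutoff
  mat$mask <- mat$mask & !bad
  if (!any(mat$mask)) stop("all bins masked by the low-coverage filter")
  mat
}

#' ICE normalization of a contact matrix
#'
#' Iterative correction: each round, every bin's bias is multiplied by its
#' relative marginal (row sum / mean row sum) and the matrix is divided by
#' the outer product of the update.  Iterations stop when the biases
#' change by less than `tol` (relative, max over bins) from the previous
#' round, or after `max_iter` rounds.  The normalized matrix is finally
#' rescaled so that the mean over valid entries is exactly 1 (an average
#' content of one interaction per cell).
#'
#' @param mat a [contact_matrix()] (typically after [filter_low_bins()])
#'   with >= 2 valid bins.
#' @param tol relative bias-change stopping tolerance (default 0.10).
#' @param max_iter maximum iterations (default 10).
#' @return Object of class `ice_result`: `biases` (per bin, `NA` on
#'   masked bins), `normalized` (a [contact_matrix()], `NA` on masked
#'   rows/columns), `n_iterations`, `converged`, `final_change`.
#' @export
ice_normalize <- function(mat, tol = 0.10, max_iter = 10) {
  stopifnot(inherits(mat, "contact_matrix"))
  valid <- which(mat$mask)
  if (length(valid) < 2) stop("need at least 2 valid bins")
  w <- mat$counts[valid, valid]
  nb <- length(valid)
  bias <- rep(1, nb)
  converged <- FALSE
  change <- NA_real_
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    s <- rowSums(w)
    if (any(!is.finite(s)) || mean(s) <= 0)
      stop("ICE diverged at iteration ", it)
    delta <- s / mean(s)
    delta[delta == 0] <- 1
    w <- w / outer(delta, delta)
    bias <- bias * delta
    change <- max(abs(delta - 1))
    if (change < tol) { converged <- TRUE; break }
  }
  scale <- mean(w)
  w <- w / scale

  n <- nrow(mat$counts)
  biases <- rep(NA_real_, n); biases[valid] <- bias
  norm <- matrix(NA_real_, n, n)
  norm[valid, valid] <- w
  out_mat <- mat
  out_mat$counts <- norm
  structure(list(biases = biases, normalized = out_mat,
                 n_iterations = it, converged = converged,
                 final_change = change, mean_scale = scale),
            class = "ice_result")
}

#' @export
print.ice_result <- function(x, ...) {
  cat(sprintf(
    "<ice_result> %d iterations (%s), final max bias change %.3g\n",
    x$n_iterations, if (x$converged) "converged" else "not converged",
    x$final_change))
  invisible(x)
}

norm_counts <- function(x) {
  if (inherits(x, "ice_result")) x$normalized else x
}

#' Contact frequency vs genomic distance
#'
#' Mean normalized count per genomic separation for a given set of loci
#' (bins), plus a random-loci baseline built from uniformly drawn valid
#' bin pairs.
#'
#' @param mat a [contact_matrix()] or [ice_normalize()] result.
#' @param loci bin indices (1-based); default: all valid bins.  Loci on
#'   masked bins are skipped (their count is reported).
#' @param n_random random bin pairs for the baseline.
#' @param seed RNG seed for the baseline.
#' @return List with `profile` (data frame `separation_bins`,
#'   `distance_bp`, `mean_count`, `n_pairs`), `baseline` (same layout),
#'   and `n_skipped` masked loci.
#' @export
distance_decay <- function(mat, loci = NULL, n_random = 2000, seed = 1) {
  mat <- norm_counts(mat)
  stopifnot(inherits(mat, "contact_matrix"))
  valid <- which(mat$mask)
  loci_in <- loci %||% valid
  n_skipped <- sum(!(loci_in %in% valid))
  loci <- intersect(loci_in, valid)
  if (length(loci) < 2) stop("need at least 2 valid loci")

  profile_of <- function(ii, jj) {
    sep <- abs(ii - jj)
    val <- mat$counts[cbind(ii, jj)]
    keep <- sep > 0 & is.finite(val)
    agg <- split(val[keep], sep[keep])
    data.frame(separation_bins = as.integer(names(agg)),
               distance_bp = as.integer(names(agg)) * mat$bin_size,
               mean_count = vapply(agg, mean, numeric(1)),
               n_pairs = lengths(agg), row.names = NULL)
  }
  pairs <- t(utils::combn(loci, 2))
  prof <- profile_of(pairs[, 1], pairs[, 2])
  base <- with_seed(seed, {
    ri <- sample(valid, n_random, replace = TRUE)
    rj <- sample(valid, n_random, replace = TRUE)
    profile_of(ri, rj)
  })
  list(profile = prof, baseline = base, n_skipped = n_skipped)
}

#' Pairwise contact counts for a locus set
#'
#' All C(n, 2) pairs of the given loci with their genomic distance and
#' (normalized) contact count — the input for cross-condition scatter
#' comparisons.
#'
#' @param mat a [contact_matrix()] or [ice_normalize()] result.
#' @param loci bin indices (1-based), >= 2.
#' @return Data frame `locus_i`, `locus_j`, `distance_bp`, `count`.
#' @export
extract_pairwise_counts <- function(mat, loci) {
  mat <- norm_counts(mat)
  stopifnot(inherits(mat, "contact_matrix"))
  if (length(loci) < 2) stop("need at least 2 loci")
  pairs <- t(utils::combn(sort(loci), 2))
  data.frame(locus_i = pairs[, 1], locus_j = pairs[, 2],
             distance_bp = (pairs[, 2] - pairs[, 1]) * mat$bin_size,
             count = mat$counts[pairs])
}

#' Log2 ratio of two contact matrices
#'
#' `log2((A + pseudocount) / (B + pseudocount))` on the intersection of
#' the two valid-bin masks; other entries are `NA`.
#'
#' @param mat_a,mat_b [contact_matrix()] objects (or [ice_normalize()]
#'   results) on identical bin tables.
#' @param pseudocount added to both matrices before the ratio.
#' @return List with `ratio` (matrix) and `mask` (joint valid bins).
#' @export
ratio_matrix <- function(mat_a, mat_b, pseudocount = 0) {
  mat_a <- norm_counts(mat_a); mat_b <- norm_counts(mat_b)
  stopifnot(inherits(mat_a, "contact_matrix"),
            inherits(mat_b, "contact_matrix"))
  if (!isTRUE(all.equal(mat_a$bins, mat_b$bins)))
    stop("bin tables differ between the two matrices")
  mask <- mat_a$mask & mat_b$mask
  n <- nrow(mat_a$counts)
  ratio <- matrix(NA_real_, n, n)
  idx <- which(mask)
  ratio[idx, idx] <- log2((mat_a$counts[idx, idx] + pseudocount) /
                          (mat_b$counts[idx, idx] + pseudocount))
  list(ratio = ratio, mask = mask)
}
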