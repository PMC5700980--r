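#' Fit a Gaussian to a distance histogram
#'
#' Least-squares fit of `A * exp(-(r - mu)^2 / (2 sigma^2))` to the
#' histogram of inter-locus 3D distances.  Physical distances between TAD
#' borders are Gaussian distributed to a good approximation, so the fitted
#' `mu`/`sigma` summarize the mean separation and its cell-to-cell
#' dispersion.
#'
#' @param distances numeric vector of distances (nm), `n >= 20`.
#' @param bin_rule histogram bin rule passed to [hist()] `breaks`
#'   (default Freedman-Diaconis) or an explicit bin width in nm.
#' @return Object of class `gaussian_fit`: `mu`, `sigma`, `amplitude`,
#'   `r_squared`, `n`, and the histogram used.
#' @export
fit_gaussian <- function(distances, bin_rule = "FD") {
  distances <- distances[is.finite(distances)]
  if (length(distances) < 20) stop("need at least 20 distances")
  if (diff(range(distances)) <= 0)
    stop("zero-width histogram: all distances equal")
  breaks <- if (is.numeric(bin_rule))
    seq(0, max(distances) + bin_rule, by = bin_rule) else bin_rule
  h <- graphics::hist(distances, breaks = breaks, plot = FALSE)
  x <- h$mids; y <- h$counts
  start <- list(A = max(y), mu = mean(distances), sigma = sd(distances))
  fit <- tryCatch(
    nls(y ~ A * exp(-(x - mu)^2 / (2 * sigma^2)), start = start,
        control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) stop(
      sprintf("Gaussian fit did not converge (starts A=%.3g mu=%.3g sigma=%.3g): %s",
              start$A, start$mu, start$sigma, conditionMessage(e)),
      call. = FALSE))
  cf <- coef(fit)
  res <- y - predict(fit)
  structure(list(mu = unname(cf["mu"]), sigma = abs(unname(cf["sigma"])),
                 amplitude = unname(cf["A"]),
                 r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
                 n = length(distances), distances = distances,
                 histogram = h),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> mu = %.1f nm, sigma = %.1f nm, R2 = %.3f, n = %d\n",
              x$mu, x$sigma, x$r_squared, x$n))
  invisible(x)
}

#' Absolute contact probability below a colocalization threshold
#'
#' The contact probability between two loci is the fraction of the fitted
#' Gaussian distance distribution lying below the colocalization distance
#' `d_c` (default 120 nm, the 99% confidence bound from single-library
#' two-color controls): `Phi((d_c - mu) / sigma)`.  An empirical mode
#' (fraction of raw distances below `d_c`) is available as a cross-check.
#' The SEM is a nonparametric bootstrap over the distances.
#'
#' @param x a [gaussian_fit()] or a raw distance vector (`n >= 20`).
#' @param d_c contact distance threshold, nm (> 0).
#' @param method `"gaussian"` (integral of the fit) or `"empirical"`
#'   (count below `d_c` / n).
#' @param sem_method `"bootstrap"` or `"none"`.
#' @param B bootstrap replicates.
#' @param seed seed for the bootstrap.
#' @param truncated renormalize the Gaussian over \[0, Inf) instead of the
#'   full real line.
#' @return Object of class `contact_estimate`: `probability`, `sem`,
#'   `d_c`, `n`, `method`.
#' @export
contact_probability <- function(x, d_c = 120,
                                method = c("gaussian", "empirical"),
                                sem_method = c("bootstrap", "none"),
                                B = 1000, seed = 1, truncated = FALSE) {
  method <- match.arg(method)
  sem_method <- match.arg(sem_method)
  if (d_c <= 0) stop("'d_c' must be > 0")

  gauss_p <- function(mu, sigma) {
    p <- pnorm((d_c - mu) / sigma)
    if (truncated) {
      p0 <- pnorm(-mu / sigma)
      p <- (p - p0) / (1 - p0)
    }
    max(0, min(1, p))
  }

  if (inherits(x, "gaussian_fit")) {
    fit <- x
    distances <- fit$distances
  } else {
    distances <- x[is.finite(x)]
    fit <- if (method == "gaussian") fit_gaussian(distances) else NULL
  }

  est <- if (method == "gaussian") gauss_p(fit$mu, fit$sigma)
  else mean(distances < d_c)

  sem <- NA_real_
  if (sem_method == "bootstrap" && !is.null(distances) &&
      length(distances) >= 20) {
    boot <- with_seed(seed, vapply(seq_len(B), function(b) {
      d <- sample(distances, replace = TRUE)
      if (method == "empirical") return(mean(d < d_c))
      # moment-based Gaussian refit: fast and adequate for an SEM
      gauss_p(mean(d), sd(d))
    }, numeric(1)))
    sem <- sd(boot)
  }
  structure(list(probability = est, sem = sem, d_c = d_c,
                 n = length(distances) %||% NA_integer_, method = method),
            class = "contact_estimate")
}

#' @export
print.contact_estimate <- function(x, ...) {
  cat(sprintf("<contact_estimate> p = %.4f (SEM %.4f) below %g nm [%s, n = %d]\n",
              x$probability, x$sem, x$d_c, x$method, x$n))
  invisible(x)
}

#' Dispersion vs distance relation
#'
#' Ordinary least squares of fitted `sigma` against fitted `mu` across
#' library pairs.  A linear relation indicates that structural variability
#' scales with physical separation, as expected from the polymer nature of
#' the chromatin fiber.
#'
#' @param fits list of [fit_gaussian()] results (>= 3).
#' @return List with `slope`, `intercept`, `r_squared`, and the points.
#' @export
dispersion_vs_distance <- function(fits) {
  if (length(fits) < 3) stop("need at least 3 Gaussian fits")
  mu <- vapply(fits, `[[`, 0, "mu")
  sigma <- vapply(fits, `[[`, 0, "sigma")
  m <- lm(sigma ~ mu)
  list(slope = unname(coef(m)[2]), intercept = unname(coef(m)[1]),
       r_squared = suppressWarnings(summary(m)$r.squared), mu = mu, sigma = sigma)
}

#' Fit a power law y = A * x^beta
#'
#' Fitted as ordinary least squares in log-log space: `A = exp(intercept)`,
#' `beta = slope`.  `r_squared` is reported in the fitted (log) space.
#'
#' @param x,y positive observations (>= 3 points).
#' @param weights optional OLS weights.
#' @return Object of class `power_law_fit`: `prefactor`, `exponent`,
#'   `r_squared`, `n`.
#' @export
fit_power_law <- function(x, y, weights = NULL) {
  if (length(x) < 3) stop("need at least 3 points")
  bad <- which(!(x > 0 & y > 0))
  if (length(bad))
    stop("non-positive values at points ", paste(bad, collapse = ", "),
         ": cannot log-transform")
  m <- if (is.null(weights)) lm(log(y) ~ log(x))
  else lm(log(y) ~ log(x), weights = weights)
  structure(list(prefactor = exp(unname(coef(m)[1])),
                 exponent = unname(coef(m)[2]),
                 r_squared = suppressWarnings(summary(m)$r.squared), n = length(x)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> y = %.4g * x^%.4f (R2 = %.4f, n = %d)\n",
              x$prefactor, x$exponent, x$r_squared, x$n))
  invisible(x)
}

#' Fit an exponential y = a * exp(k x)
#'
#' Ordinary least squares of `log(y)` against `x`; `r_squared` is in the
#' fitted (log) space.
#'
#' @param x observations; `y` must be positive.
#' @param y positive responses (>= 3 points).
#' @return Object of class `exponential_fit`: `scale`, `rate`, `r_squared`.
#' @export
fit_exponential <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 points")
  bad <- which(!(y > 0))
  if (length(bad))
    stop("non-positive values at points ", paste(bad, collapse = ", "),
         ": cannot log-transform")
  m <- lm(log(y) ~ x)
  structure(list(scale = exp(unname(coef(m)[1])),
                 rate = unname(coef(m)[2]),
                 r_squared = suppressWarnings(summary(m)$r.squared), n = length(x)),
            class = "exponential_fit")
}

#' Scaling exponent of physical vs genomic distance
#'
#' For each group (chromatin state x cell type), fits the power law
#' `d_3D = A * d_kb^beta` to the mean physical distance at each genomic
#' length, and returns the prefactor-normalized distances `d_3D / A` used
#' for overlay plots.  A random-coil polymer gives beta = 1/2; an
#' equilibrium globule gives beta = 1/3.
#'
#' @param samples data frame with columns `d_kb`, `d_nm`, and optionally
#'   grouping columns `state` and/or `cell_type`.
#' @return List per group with `fit` (a [fit_power_law()] result), the
#'   per-length `means` (with SEM), and `normalized` mean distances.
#'   Groups with fewer than 3 genomic lengths are skipped with a warning.
#' @export
scaling_exponent <- function(samples) {
  stopifnot(all(c("d_kb", "d_nm") %in% names(samples)))
  gcols <- intersect(c("state", "cell_type"), names(samples))
  key <- if (length(gcols)) interaction(samples[gcols], drop = TRUE)
  else factor(rep("all", nrow(samples)))
  out <- list()
  for (g in levels(key)) {
    sub <- samples[key == g, ]
    agg <- do.call(rbind, lapply(split(sub, sub$d_kb), function(s)
      data.frame(d_kb = s$d_kb[1], mean_nm = mean(s$d_nm),
                 sem_nm = sd(s$d_nm) / sqrt(nrow(s)), n = nrow(s))))
    if (nrow(agg) < 3) {
      warning(sprintf("group '%s' has < 3 genomic lengths; skipped", g))
      next
    }
    fit <- fit_power_law(agg$d_kb, agg$mean_nm)
    agg$normalized <- agg$mean_nm / fit$prefactor
    out[[g]] <- list(fit = fit, means = agg)
  }
  out
}

#' Expected number of resolvable foci per cell
#'
#' With `n` labeled loci and homolog pairing probability `p`, a paired
#' locus appears as one focus and an unpaired locus as two, so the
#' expected number of resolvable foci (absent long-range clustering) is
#' `n * (2 - p)`.
#'
#' @param n_loci number of labeled loci per chromosome.
#' @param p pairing probability in \[0, 1\].
#' @return Object of class `pairing_model`: `n_loci`, `p`,
#'   `expected_foci`.
#' @export
expected_resolvable_foci <- function(n_loci, p) {
  stopifnot(p >= 0, p <= 1, n_loci >= 1)
  structure(list(n_loci = n_loci, p = p,
                 expected_foci = n_loci * (2 - p)),
            class = "pairing_model")
}

#' Relate Hi-C counts to absolute contact probability
#'
#' Fits both an exponential and a power-law model of normalized Hi-C
#' counts versus microscopy-derived absolute contact probabilities and
#' reports each model's coefficients and R-squared; no model selection is
#' imposed (both describe the data comparably well).
#'
#' @param hic_counts,probabilities paired positive observations
#'   (>= 4 points).
#' @return List with `power_law`, `exponential`, and `r_squared`
#'   comparison.
#' @export
hic_vs_probability <- function(hic_counts, probabilities) {
  if (length(hic_counts) != length(probabilities))
    stop("inputs must be paired")
  if (length(hic_counts) < 4) stop("need at least 4 points")
  pl <- fit_power_law(probabilities, hic_counts)
  ex <- fit_exponential(probabilities, hic_counts)
  list(power_law = pl, exponential = ex,
       r_squared = c(power_law = pl$r_squared,
                     exponential = ex$r_squared))
}
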