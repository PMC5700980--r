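---
title: "Models and methods behind chromostoch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chromostoch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

chromostoch quantifies how stochastic, low-frequency contacts organize
chromosomes across scales, combining three experimental readouts that are
analyzed jointly in *Drosophila* nuclei: 3D structured-illumination
microscopy (3D-SIM) of fluorescently labeled TAD borders, single-molecule
localization microscopy (dSTORM) of histone marks, and Hi-C contact
matrices. Every analysis stage has a matching synthetic-data generator
with recorded ground truth, so the pipeline is testable end to end
without any external data. This vignette describes the models, the
tunable parameters that matter, and the numerical and design choices
made where the published procedures left the design open.

## 1. The imaging model and the foci pipeline

**Voxel geometry.** Stacks are `(z, y, x)` arrays with 39.5 nm lateral
and 125 nm axial voxels, matching a reconstructed 3D-SIM acquisition.
The stated optical resolutions (~120 nm lateral, ~300 nm axial FWHM) are
converted to Gaussian PSF sigmas via `sigma = FWHM / 2.355`, giving the
generator defaults `psf_sigma_xy = 51` nm and `psf_sigma_z = 127` nm.
Loci are rendered as anisotropic Gaussian blobs sampled on the voxel
grid; the DAPI-like channel is a smooth sigmoid ellipsoid shell; camera
noise is additive Gaussian (`noise_level`, counts), clipped at zero.

**Nucleus segmentation** (`segment_nucleus`) low-pass filters the DAPI
channel, computes one threshold per z plane, and applies the average of
the per-plane thresholds to the whole 3D region, keeping the largest
connected component. Three open choices were resolved as follows:

* The per-plane threshold rule is Otsu's between-class-variance
  criterion (the cited rule is not printed in the source methods);
  `mean + k*sd` is available as an alternative. When the between-class
  variance plateaus (two-valued planes) the middle of the plateau is
  taken, not its first bin.
* The low-pass filter is lateral-only by default
  (`lowpass_sigma_nm = 150`, `lowpass_sigma_z_nm = 0`). Blurring across
  125-nm planes pushes intensity into planes that contain no nucleus,
  whose near-zero thresholds then corrupt the average; with a lateral
  filter such planes stay flat and are excluded. On a noise-free hard
  ellipsoid the recovered volume is within 5% of the analytic volume.
* Planes whose threshold is below 25% of the maximum plane threshold are
  treated as containing no nuclear signal (noise floor) and excluded
  from the average.

**Foci detection** (`detect_foci`) thresholds in-mask voxels at the
Kapur maximum-entropy level — the 256-bin histogram cut maximizing the
sum of foreground and background Shannon entropies — then labels
26-connected components (6-connectivity available) and reports each
component's intensity-weighted center of mass in nm. Components of fewer
than `min_voxels = 2` voxels are discarded as single-voxel noise (a
robustness choice, not a published constant). Two blobs closer than
about one voxel merge into a single focus; this is inherent to
connected-component detection and mirrors what the microscope itself
cannot resolve.

**Distances and shape statistics.** `pair_border_distances` records, for
each focus in one channel, the 3D distance to the nearest focus in the
other channel (each A focus contributes one distance; a symmetrized
option exists). `pr_distribution` histograms all pairwise distances with
left-closed bins `[a, b)`; the population p(r) is the mean of per-cell
normalized distributions on shared bins. `D_max` is the smallest
distance at which the cumulative p(r) area reaches 97% (linear
interpolation inside the crossing bin); `R_g` is the unweighted RMS
distance of foci from their centroid.

## 2. Distance statistics and contact probability

Inter-border 3D distances are well described by a normal distribution,
so `fit_gaussian` fits `A exp(-(r-mu)^2 / 2 sigma^2)` to the distance
histogram (Freedman–Diaconis bins by default) by nonlinear least
squares. The **absolute contact probability** is the fraction of the
fitted Gaussian below the colocalization distance `d_c = 120` nm (the
99% confidence bound of two-color single-library controls; the
colocalization floor itself is ~40 nm): `Phi((d_c - mu)/sigma)`,
normalized over the full real line by default with a truncated-at-zero
option. The standard error is a seeded nonparametric bootstrap
(`B = 1000`) over the distances; inside the bootstrap the Gaussian is
refit by moments, which is accurate for an SEM and three orders of
magnitude cheaper than refitting `nls` per replicate. An empirical mode
(`count below d_c / n`) provides a cross-check and agrees with the
integral estimate within two bootstrap SEMs on well-specified samples.

Power laws (`d_3D = A d_kb^beta`, Hi-C counts vs probability) are fitted
by ordinary least squares in log–log space — deterministic and
closed-form; R² is reported in the fitted space. The ideal-chain anchor:
a freely jointed chain with fixed bond length has
`E[R^2] = L b^2`, so the scaling exponent of mean distance versus
genomic length is 1/2, while an equilibrium globule gives 1/3;
`scaling_exponent` recovers 0.5 ± 0.05 on 500 simulated chains spanning
two decades of subchain length. Normalizing distances by the fitted
prefactor `A` makes data sets overlayable, with the normalized value at
`d_kb = 1` equal to 1 by construction.

The **resolvable-foci model** is `n_loci * (2 - p)`: a homolog-paired
locus yields one focus, an unpaired one two. For 69 labeled borders and
pairing frequencies of 0.60–0.70 this gives 89.7–96.6 expected foci —
the 90–100 band — assuming no long-range clustering, which is exactly
what makes observed deficits in foci counts informative.

## 3. SMLM analysis: CBC and Voronoi compartments

**Coordinate-based colocalization** (`cbc`) computes, for each
channel-A localization, cumulative neighbor counts `N_AA(r)` and
`N_AB(r)` on a radius schedule (default 10–300 nm in 10-nm steps; the
schedule is not a published constant and `Rmax = 300` nm matches the
compartment length scale). The gradients `N(r)/r^2`, anchored at
`Rmax`, are rank-correlated (Spearman), and the correlation is weighted
by `exp(-E_AB/Rmax)` with `E_AB` the nearest-B distance. Points with no
neighbors at `Rmax` get `CA = 0` (counted and reported). A B point
exactly coincident with the evaluated A point is treated as the same
molecule: excluded from the count gradient while keeping `E_AB = 0`, so
identical channels give `CA = 1` exactly. Co-occurrence is the fraction
of localizations with `CA > 0.5`.

**Voronoi segmentation** (`voronoi_segment`) computes the bounded
Voronoi diagram of the field (compiled half-plane-clipping kernel;
boundary cells are clipped to the field rectangle, since infinite cells
have no area). Polygon density is the inverse polygon area; polygons
denser than `density_factor` times the average density `N / field area`
are merged with touching supra-threshold polygons, and merged groups
with at least `min_polygons` members become compartments.

The defaults required genuine calibration. The only published constraint
is a null: a spatially random field must segment nothing. With raw
per-polygon densities, a threshold factor of 2 and a minimum of 3
polygons, a uniform field of 10^4 points yields tens of spurious
compartments — ~15% of Poisson–Voronoi cells are individually denser
than twice the mean, and they percolate into triples easily. We
therefore (i) smooth each polygon's density over itself and its
first-rank neighbors (`(1 + k) / (A_i + sum of neighbor areas)`), in the
spirit of the original tessellation-segmentation method, and (ii) set
`density_factor = 2.5` and `min_polygons = 12`. This combination yields
zero compartments across 50 seeded uniform fields of 10^4 points while
recovering planted 100–500 nm discs at 20× density contrast with ~5%
median diameter error (the acceptance bound is 15%). These two defaults
were fixed against the null once and not revisited. Raw density is
available via `smooth_rank1 = FALSE`.

Compartment sizes are **equivalent diameters**: the merged outline is
rasterized on a 5-nm grid, interior holes are filled, and
`d = 2 sqrt(area/pi)`. Size distributions are reported as probability
density histograms whose bar areas sum to 1. Note one idealization that
does *not* hold exactly: the outermost ring of polygons of a cluster
borders the sparse surround, so its cells are large and fall below
threshold; a compartment therefore captures typically 80–95% of its
localizations, not 100%.

**Pixel-based controls** (`render_and_correlate`) render each channel as
a 2D count image (default 20-nm pixels), blur by the median localization
precision, and report the Pearson correlation over pixels plus Manders
`M1`/`M2`. Manders masks default to any-signal (> 0) on the unblurred
count images, so identical channels give `M1 = M2 = 1`; Otsu masks are
optional.

## 4. Genomic domains and the clustering percentage

`peaks_to_signal` resamples ChIP peaks into a continuous binned signal
(default 10 bp), overlap-weighted so partial bins contribute
fractionally. `call_domains` log-compresses (`log(signal + 1)`; the
log's base and zero-handling are not published — natural log with a +1
offset is used and configurable), thresholds at 0.1 of the log-maximum
(permissive by design: a peak at 1% of the maximum intensity survives,
which a test asserts), keeps maximal supra-threshold runs longer than
2 bp, and fuses domains separated by less than 1 kb. The procedure is
idempotent, fusion is transitive, and raising the threshold never
increases coverage. Genomic lengths convert to physical sizes through
the imaging-derived power law per chromatin state:
`size_nm = A (length_kb)^beta`.

The **clustering percentage** compares large (> 150 nm) compartments
observed by imaging with those predicted from genomic domain sizes:
`max(0, 1 - N_pred/N_obs) * 100` per cell, aggregated with its SD. The
published sentence defines only "the ratio between the numbers of
clusters larger than 150 nm from ChIP-seq vs microscopy"; the direction
and normalization used here are our definition, chosen so that "almost
no clustering" corresponds to a ratio near 1 and 0%. A calibration
factor scales the genome-wide predicted count to a per-cell expectation.

## 5. Hi-C matrices

Dense single-chromosome matrices (text + BED3 bins) are validated on
read: square, finite, and symmetric — asymmetries below 1% are averaged
away, larger ones are errors. `filter_low_bins` masks zero-marginal bins
and those below the 2nd percentile of nonzero marginals (the published
pipeline names no cutoff); the percentile uses the inverse-ECDF quantile
so a detached low-coverage group is masked in its entirety.

`ice_normalize` implements iterative correction: each round multiplies
the running biases by the relative marginals and divides the matrix by
the update's outer product, stopping when the maximum relative bias
change drops below 10% or after 10 iterations ("max" is the stricter
reading of the published 10% rule, which names no norm). The result is
rescaled so the mean over valid entries is exactly 1 ("one interaction
per cell"), and is invariant to the input scale. One property worth
stating precisely: on a distance-decay matrix, even without biases the
marginals are unequal (edge bins see fewer partners), and any
marginal-equalizing method absorbs that into its biases. Planted-bias
recovery is therefore exact (within the stopping tolerance) only on
flat-expectation matrices; on decaying matrices the meaningful contracts
are the mean-1 rescale and near-equal marginals, both tested.

`distance_decay` aggregates normalized counts by genomic separation for
a locus set and for a random-pair baseline; on noise-free generator
matrices the log–log slope reproduces the planted decay exponent within
0.05. `ratio_matrix` compares conditions as `log2((A+e)/(B+e))` on the
joint valid-bin mask.

## 6. What the synthetic data does and does not emulate

The generators state the world the tests live in: Gaussian-distributed
inter-border distances (default `mu = 400`, `sigma = 150` nm — chosen
as a realistic TAD-border separation; the source figures' exact values
are not in the extracted text), 60–70% homolog pairing, ~69 loci per
chromosome, compartments of tens to hundreds of nm over Poisson
background, alternating epigenetic domains, and multiplicative
lognormal Hi-C bin biases over a power-law distance decay. The homolog
offset for unpaired loci is not published anywhere; it defaults to an
isotropic offset with truncated-normal length (mean 800 nm, sd 200 nm)
and is an explicit parameter.

Not emulated: optics beyond a Gaussian PSF (no SIM reconstruction
artifacts), fluorophore blinking/photophysics, drift or chromatic
aberration (assumed corrected upstream), sequencing reads, and 3D SMLM.
A green test therefore establishes that the estimators recover the
stated world's parameters at the stated tolerances — not that they are
robust to instrument pathologies outside that world.

## 7. Numerical choices and degenerate inputs

* All generators are pure functions of (parameters, seed); the RNG state
  of the caller is saved and restored, and pipeline stages derive child
  seeds from the single config seed.
* Kapur and Otsu thresholds use 256-bin histograms; constant inputs are
  degenerate (error for the threshold functions; "no foci"/"no nucleus"
  for the detectors, where emptiness is a valid result).
* Voronoi: exactly duplicated localizations are deterministically
  jittered by sub-nm amounts so cells stay well defined; collinear
  fields are rejected.
* Gaussian fit non-convergence raises an error carrying the initial
  guesses; all-equal distance vectors are a zero-width histogram error.
* `dmax_from_pr(fraction = 1)` returns the upper edge of the last
  occupied bin (the interpolation's exact limit).
* The imaging pipeline computes population statistics on generator
  geometry for all cells and demonstrates the full render→detect path on
  `n_image_cells` cells; rendering every cell would add minutes of
  runtime without changing any tested statistic.

## 8. Known limitations

* Voronoi areas are exact, but equivalent diameters inherit the 5-nm
  raster (sub-2% at the default grid).
* The bounded-Voronoi adjacency comes from surviving clip edges; a
  point-touching (degenerate) contact can register as adjacency. This
  has no measurable effect at SMLM densities.
* CBC is O(N_A × (N_A + N_B)); fields beyond ~10^5 points per channel
  call for spatial indexing that is not implemented.
* Dense matrices only; genome-wide multi-chromosome balancing and
  sparse formats are out of scope, as are TAD calling and 3D model
  reconstruction.
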