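Package: chromostoch
Title: Stochastic Multiscale Chromosome Organization from Super-Resolution
    Imaging and Hi-C
Version: 0.1.0
Authors@R:
    person("Mara", "Valente", email = "mara.valente@posteo.net",
           role = c("aut", "cre"))
Description: Quantitative analysis of single-cell chromosome organization
    combining super-resolution microscopy with chromosome conformation
    capture. Detects fluorescent foci in 3D structured-illumination stacks,
    estimates absolute contact probabilities between topological domain
    borders from Gaussian-fitted distance distributions, fits polymer
    scaling exponents, segments nanoscale epigenetic compartments from
    single-molecule localization data by Voronoi tessellation, performs
    coordinate-based colocalization, calls genomic domains from ChIP peak
    tracks and predicts their physical sizes, and normalizes dense Hi-C
    contact matrices by iterative correction. A synthetic-data module
    generates every input with known ground truth so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
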