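Package: stemAtlas
Title: Statistical Intensity Atlases of Vascular Bundles in Plant Stem Cross-Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds statistical maps of vascular bundle intensity within a
    reference plant-stem cross-section from replicated images. Provides polygon
    primitives (pixel-chain tracing, bilateral symmetry alignment, arc-length
    resampling, Douglas-Peucker simplification, ray casting), segmentation of
    stem slab scans and macroscopy sections, shape-contour principal component
    analysis with nested analysis of variance, a per-coordinate linear contour
    model yielding a reference (atlas) contour, morphological detection of
    vascular bundles (alternate sequential filtering, extended minima,
    watershed), polar spatial normalisation of point patterns onto the
    reference contour, and edge-corrected Gaussian kernel intensity estimation
    with group-wise averaging. A synthetic study generator produces stem
    contours with controlled genotype, cutting-position and stem effects,
    inhomogeneous Poisson and hard-core bundle patterns, and rendered section
    images for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    Rcpp,
    jsonlite,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
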