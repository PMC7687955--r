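Package: skinet
Title: Supervised Self-Organizing Maps and Spectral Unmixing for Raman
    Tissue Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for chemometric analysis of Raman microspectroscopy maps
    of neural tissue. Provides a synthetic spectral-map generator with
    group-dependent band effects, preprocessing (nearest-neighbour cosmic-ray
    removal, iterative lower-envelope spline baseline subtraction, map
    averaging, vector normalisation, stratified splitting), a from-scratch
    supervised self-organizing map on a hexagonal grid with cosine-similarity
    best-matching-unit search, discriminant feature extraction (SOMDI),
    k-fold cross-validation and repeated-initialization confusion matrices,
    non-negative least-squares unmixing of tissue spectra against a component
    library with one-way ANOVA group comparison, and band-intensity ratio
    imaging of spectral maps.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    pracma,
    ggplot2,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
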