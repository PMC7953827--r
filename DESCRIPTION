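Package: ssmdr
Title: Spectra Similarity Matrices and Dimensionality Reduction for
    Ambient-Ionization Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quality control and class-structure analysis of
    ambient-ionization mass-spectrometry profiles of tissue samples.
    Spectra are binned onto a fixed m/z grid, denoised (moving-median
    filter, rolling-minimum baseline subtraction), and compared either
    after top-N peak thresholding or after dimensionality reduction
    (PCA, PLS-DA, non-negative matrix factorization, Isomap, UMAP,
    diffusion maps), all behind one fit/transform contract with
    out-of-sample projection.  Cosine spectra-similarity matrices (SSMs)
    ordered by acquisition date or by diagnosis are summarized by a
    quantitative within-block versus between-block contrast statistic
    with a permutation test, quantifying batch effects and class
    separation.  A seeded synthetic-spectra generator emulates the
    nested patient/sample/scan structure, polarity-dependent peak
    stability and acquisition-date batch effects of clinical profiling
    studies, so the full comparison pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mixOmics,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    uwot
LinkingTo:
    Rcpp
Suggests:
    mzR,
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
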