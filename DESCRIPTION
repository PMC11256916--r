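Package: scgraphdec
Title: Graph Deconvolution of Cell-Type-Specific Single-Cell Hi-C Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts cell-type-specific pseudo-bulk single-cell Hi-C contact
    maps from pseudo-bulk scRNA-seq tracks by deconvolving a bulk Hi-C contact
    map with a graph attention network guided by expression, CTCF motif and
    CpG signals. Includes the full preprocessing stack (library-size
    normalization, eigenvalue soft-threshold denoising, min-max scaling,
    tiling), Laplacian eigenvector positional encodings, a neural
    encoder-decoder trained by backpropagation, Hi-C similarity metrics
    (GenomeDISCO-style concordance, stratum-adjusted correlation, insulation
    based TAD boundary calling with F1 comparison) and a synthetic co-assay
    generator so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp,
    GenomicRanges,
    IRanges,
    rtracklayer
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
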