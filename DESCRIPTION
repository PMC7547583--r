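Package: spcnet
Title: Metaproteomic Spectral-Count Differential Abundance and
    Co-Abundance Network Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end inference chain for shotgun metaproteomics
    spectral-count data from multi-group designs: NSAF protein
    quantification with downshifted-Gaussian imputation, aggregation of
    protein counts to taxa at their lowest assigned rank, low-count
    filtering, TMM between-sample normalization, moment-based
    Poisson-Tweedie two-sample differential-abundance testing across all
    pairwise phenotype comparisons with Benjamini-Hochberg control,
    mutual-information bacterial co-abundance network inference (C3NET
    and its bagged ensemble BC3NET), MST2 backbone reduction, topology
    statistics, and percentile-based hub detection.  A synthetic
    metaproteome generator with planted effects and co-abundance modules
    provides a fully self-contained test bed.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
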