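Package: chromogrow
Title: Single-Cell 3D Chromatin Ensembles from Population Hi-C
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transforms binned population Hi-C contact maps into large
    ensembles of single-cell 3D chromatin conformations. A confined,
    self-avoiding random-polymer ensemble grown by sequential importance
    sampling with checkpoint resampling serves as a physical null model;
    a Bag-of-Little-Bootstraps test against this null isolates specific
    interactions at a controlled false discovery rate; a sequentially
    grown, Hi-C-concordant constrained ensemble reconstructs single-cell
    conformations from the specific interactions; and structural
    analytics quantify heterogeneity, single-cell TAD-like domains,
    boundary-probability enrichment at protein binding peaks, virtual 4C
    tracks, and many-body contact fractions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    limma,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
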