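Package: triggerscan
Title: Nomination of Target-Directed MicroRNA Degradation Trigger Sites
    from Chimeric AGO-CLASH Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate trigger sites for target-directed
    microRNA degradation (TDMD) from chimeric miRNA:target interaction
    data such as AGO-CLASH / chimeric eCLIP. Implements seed-match
    classification, intermolecular RNA-RNA duplex prediction under a
    nearest-neighbor energy model, per-site pairing-architecture metrics
    (central bulge length, 3' pairing run, 3' minimum free energy), a
    six-criterion filter cascade with 3'-MFE ranking, annotation-based
    region classification, phyloP-style conservation scoring, a
    target-repression CDF statistic, and a synthetic-data generator with
    planted ground-truth sites for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    GenomeInfoDb
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
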