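Package: serscan
Title: Motif-Based Prediction and Characterization of Ciliate Ser Surface Antigen Gene Families
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for genome-wide prediction of the polymorphic Ser
    (serotype / immobilization antigen) gene family of Tetrahymena
    thermophila and similar cysteine-rich GPI-anchored surface protein
    families. Scans a proteome for length-constrained periodic
    cysteine-block motifs, filters candidates with a rule-based
    GPI-anchor signal classifier (omega site, polar spacer, hydrophobic
    tail), decomposes candidates into repeat blocks and reports
    cysteines per block, assigns subtypes by neighbor-joining phylogeny
    with bootstrap against labelled reference sequences, detects
    same-subtype tandem gene arrays on scaffolds, and clusters
    developmental expression profiles by k-means under Pearson
    correlation distance. Includes deterministic synthetic-fixture
    generators with machine-readable ground truth so that every stage
    is testable without downloads, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    rtracklayer,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
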