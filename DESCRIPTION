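Package: taxoresolve
Title: Genome-Based Taxonomic Revision of Bacterial Families
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for whole-genome prokaryotic taxonomy:
    pairwise genomic similarity metrics (ANI, AAI, digital DDH,
    codon-position similarities, 16S identity), core-genome phylogeny
    with bootstrap support and low-support collapsing, classification of
    genera as mono-, para-, or polyphyletic, rule-based species-, genus-
    and family-level reclassification proposals with an evidence trail,
    marker-gene phenotype prediction, and a placement workflow for new
    genomes.  Includes a synthetic-data generator so that every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    phangorn,
    Rcpp,
    jsonlite,
    Matrix,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
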