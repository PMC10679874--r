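Package: spliceopanel
Title: Transcriptomic and Genomic Identification of Spliceosomal Genes
Version: 0.1.0
Authors@R:
    person("Panel", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reusable desk-scale pipeline for identifying a curated panel of
    spliceosomal protein and snRNA genes in a non-model transcriptome and
    genome: six-frame translated Smith-Waterman search with Karlin-Altschul
    E-values, reciprocal best-hit orthologue assignment, cross-platform open
    reading frame verification and chimera flagging, spliced-leader
    trans-splicing detection and prevalence estimation, genomic snRNA
    tandem-array calling, and alignment-based transfer of splicing-modulator
    contact residues. Ships a seeded synthetic-data generator with full
    ground-truth tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
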