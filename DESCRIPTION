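Package: mitorecomb
Title: Repeat-Mediated Recombination and Structural Analysis of Plant
    Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the structural analysis of circular plant
    mitochondrial genomes from long reads: detection of simple sequence
    repeats, tandem repeats and dispersed repeat pairs on circular
    molecules; enumeration of the alternative genome conformations that
    repeat pairs mediate through homologous recombination; classification
    of long reads by the conformation whose recombination junction they
    span; per-repeat read-support tables and inference of the implied
    multipartite (master circle plus subgenomic circles) genome model.
    Also computes pairwise shared-DNA fractions between genomes,
    identifies plastid-derived fragments (MTPT) in mitochondrial
    genomes, and generates fully ground-truthed synthetic genomes and
    simulated long reads for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
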