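Package: taxprimer
Title: Taxon-Targeted 16S rDNA Primer Design and In-Silico Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing taxon-targeted (archaea-specific) 16S rDNA
    primers from whole genomes and evaluating them computationally. Locates and
    extracts the 16S locus from genomes by local alignment to a reference gene,
    reorienting minus-strand copies; builds a deterministic center-star multiple
    alignment and profiles per-column conservation; derives degenerate IUPAC
    consensus primers with constant 5' tails, nearest-neighbor melting
    temperatures and Tm-matched 5' trimming; predicts amplicons by in-silico PCR
    with a mismatch-tolerant, 3'-anchored binding model; classifies long
    amplicon reads against a reference panel under length, reference-coverage
    and identity thresholds; and compares classifiers by per-rank agreement.
    Includes a fully seeded synthetic-community generator (templates with
    conserved and hypervariable blocks, genomes embedding the gene on either
    strand, noisy long reads) so the whole workflow is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
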