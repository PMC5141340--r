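Package: neopseudo
Title: Pseudogenization Dynamics on Young Neo-Sex Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for comparative pseudogene analysis on recently formed
    (neo-) sex chromosomes and their autosomal orthologues. Classifies gene
    copies as functional or pseudogenized from annotation and expression
    evidence, assigns pseudogenization events to branches of a four-taxon
    species tree by parsimony, compares time-calibrated pseudogenization
    rates with chi-square tests, estimates branch-specific dN/dS
    (Nei-Gojobori counting with parsimony ancestral sequence
    reconstruction), analyses female-to-male expression ratios and
    tissue-specific expression, and tests for association between
    pseudogenization and sexually antagonistic gene effects. A
    synthetic-data generator produces complete, ground-truthed input
    bundles (GFF3, FASTA, expression and ortholog tables) so every stage
    of the pipeline can be exercised without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
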