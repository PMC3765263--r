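Package: mircycle
Title: Small RNA Sequencing Analysis of Hair-Follicle Cycling miRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a small RNA sequencing workflow for
    profiling microRNAs across the anagen, catagen and telogen stages of the
    hair-follicle cycle: read cleaning with per-category contamination
    accounting, exact-match genome mapping with priority-based annotation,
    conserved miRNA quantification, hairpin-based novel miRNA prediction under
    Mireap-style criteria with minimum-free-energy folding, rule-based miRNA
    target prediction, two-library differential expression with the
    Audic-Claverie exact test, and hypergeometric GO/pathway enrichment.
    Includes a synthetic-data generator that plants known miRNAs, contaminant
    classes and differential expression so every stage can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
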