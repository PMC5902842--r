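Package: genesetqc
Title: Cross-Genotype Gene-Set Comparison and Annotation Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing predicted gene sets between genotypes of the
    same species and for quality control of genome annotation. Implements a
    three-stage best-alignment cascade (protein, coding sequence, whole
    genome) that classifies every query gene model as identical, contained,
    binned by percent identity, matched at the CDS level only, encapsulated
    in or overlapping an untranslated region, present without a match, or
    missing from the genome; reciprocal best-match detection; per-base
    RNA-seq coverage support classification with quality tagging; structural
    annotation lint; stable locus naming; tandem-duplicate detection;
    assembly statistics; and a seeded synthetic-data generator that plants
    known comparison categories, identity bins and coverage classes for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
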