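Package: poolscreen
Title: Pooled CRISPRi Fitness Screen Analysis for Conditional Gene Essentiality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of pooled CRISPR interference (CRISPRi)
    fitness screens in bacteria, built around an aerobic/anaerobic
    conditional-essentiality design. Counts guide spacers in amplicon reads by
    exact 20-mer matching, normalizes counts against non-targeting controls,
    estimates a trended negative-binomial dispersion, tests per-spacer log2
    fold changes, aggregates guides to gene-level calls (median LFC plus
    Stouffer-combined significance) with transcription-unit aware reporting,
    merges predicted transcripts into transcription units by single-linkage
    clustering of a pseudo-distance, models follow-up phenotypes (growth-curve
    fitness, multiplicative drug-gene synergy, spot-dilution scores, mutation
    frequencies), and summarizes essential-gene conservation across comparator
    species from orthogroup tables. A negative-binomial screen simulator with
    known ground truth supports calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    methods,
    stats,
    utils,
    pracma,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
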