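Package: ccr5flux
Title: Case-Control Association and Monocyte Calcium-Flux Analysis for the
    CCR5 -2459 A>G Promoter Polymorphism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for studying the CCR5 promoter
    polymorphism rs1799987 (-2459 A>G) in Löfgren's syndrome: case-control
    SNP association (allele, genotype and carriership contingency tests,
    Hardy-Weinberg equilibrium, Wald odds-ratio confidence intervals),
    flow-cytometric quantification of CCR5 surface expression on gated
    CD14+ monocytes (isotype-anchored positivity thresholds, percent
    positive, median fluorescence intensity, monocyte subset labels), and
    kinetic scoring of intracellular calcium responses to MIP-1alpha and
    fMLP from binned fluo-4 event streams (AUC/time frames, baseline-net
    responses, positive-control normalisation, responder classification).
    Includes a synthetic-data generator that emulates the study's genotype
    cohorts and per-event cytometry so every stage is testable without
    access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
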