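Package: rewirekit
Title: Rare Regulatory Variants and Patient-Specific Promoter-Enhancer Rewiring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of rare regulatory variants and
    patient-specific promoter-enhancer chromatin rewiring from promoter
    capture Hi-C interactomes matched with whole-genome sequencing.
    Classifies gain- and loss-of-interaction events by genotype concordance
    and cohort specificity, annotates variants with exact position weight
    matrix motif p-values and gain/loss-of-motif calls, tests allele-specific
    interaction imbalance with a beta-binomial model and two-stage logit
    p-value combination, and runs minor-allele-frequency-stratified cell-type
    enrichment tests against single-cell expression profiles. Ships a
    synthetic cohort generator with planted ground truth so every stage is
    testable end to end without controlled-access patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
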