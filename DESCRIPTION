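Package: exburden
Title: Two-Stage Rare-Variant Burden Discovery for Case-Control Exomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for two-stage rare-variant discovery in
    case-control exome studies: genotype-, variant- and sample-level
    quality-control cascades; allele-frequency classing and nested
    loss-of-function / strictly-damaging / broadly-damaging variant masks;
    single-variant likelihood-ratio tests and gene-based burden, SKAT and
    SKAT-O score tests for binary traits; score-statistic meta-analysis
    across stages; leave-one-out driver detection and stage-2 candidate
    selection; an external-control functional-to-synonymous ratio test;
    permutation gene-set enrichment with exome-wide control; and a
    synthetic cohort generator that emulates the two-stage study design
    for end-to-end testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite
Config/testthat/edition: 3
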