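Package: ctdnaconcord
Title: Tumor-Informed Plasma ctDNA Concordance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired tumor-tissue and plasma cell-free DNA
    targeted sequencing in early-stage lung cancer. Implements three-step somatic
    variant filtering (depth, variant coverage, variant allele frequency and
    binomial p-value thresholds, a Fisher strand-bias proxy, and hotspot-panel
    restriction), germline subtraction against matched white-blood-cell calls,
    per-pair mutation matching with fractional allocation of true/false
    positive/negative pair-equivalents, aggregate concordance, sensitivity,
    specificity and plasma positive predictive value with Wilson intervals,
    reference-standard limit-of-detection simulation, and rank-based association
    of cfDNA concentration with clinical features and serum tumor markers. Ships
    a synthetic-cohort generator emulating published cohort marginals so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
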