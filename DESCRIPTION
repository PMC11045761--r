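Package: faersignal
Title: Disproportionality Signal Detection for FAERS Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for pharmacovigilance signal detection on
    FAERS-style quarterly ASCII extracts: report ingestion and joining,
    rule-based deduplication, target-drug cohort construction, custom
    standardized MedDRA query (SMQ) classification, reporting odds ratio
    (ROR) and shrinkage information component (IC) disproportionality
    statistics with signal flagging, time-to-onset summaries, and
    baseline-characteristics / outcome-severity tables. Ships a synthetic
    spontaneous-report generator with known ground truth so every stage is
    testable without access to the full database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
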