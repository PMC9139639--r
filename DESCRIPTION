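Package: ctdnaRWE
Title: Claims-Based Analysis of ctDNA-Guided Therapy in Metastatic Colorectal Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for real-world-evidence analyses of circulating tumor DNA
    (ctDNA) panel testing in metastatic colorectal cancer using payer claims
    data. Reconstructs lines of therapy from claim streams with gap and
    regimen-change rules, applies cohort eligibility filters (pre-treatment
    clean window, test-to-line timing, metastatic confirmation), classifies
    ctDNA profiles for clinical actionability under a fixed six-biomarker
    rule set (RAS, BRAF V600E, ERBB2 amplification, NTRK1 fusion, MSI-high,
    tumor sidedness), labels post-test therapy as molecularly informed or
    matched, and analyses time to treatment discontinuation and overall
    survival with Kaplan-Meier, log-rank and Cox proportional-hazards
    methods. Includes a calibrated synthetic-cohort generator so the full
    pipeline can be exercised without access to proprietary claims databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
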