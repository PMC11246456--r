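Package: faersignal
Title: Disproportionality Signal Detection and Prioritization for FAERS
    Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for the FDA Adverse Event
    Reporting System (FAERS) quarterly ASCII extracts: reads and links the
    seven case-level tables, deduplicates case versions, builds a
    suspect-drug cohort restricted to a MedDRA System Organ Class, screens
    Preferred-Term level reporting odds ratios (ROR) with Wald confidence
    intervals and the ROR025/count signal rule, compares serious against
    nonserious reports, prioritizes signals with a five-feature
    semi-quantitative clinical priority score, and characterizes
    time-to-onset with a two-parameter Weibull shape-parameter test. A
    seeded synthetic FAERS generator with analytic ground truth makes every
    stage testable without downloading the database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    jsonlite,
    yaml
Suggests:
    fitdistrplus,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
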