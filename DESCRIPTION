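Package: rorscreen
Title: Inverse Pharmacovigilance Signal Screening for Drug Repurposing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for case/non-case disproportionality
    screening of spontaneous adverse-event reports, oriented toward inverse
    signals (reporting odds ratio below one) as drug-repurposing hypotheses.
    Reads FAERS-style DEMO/DRUG/REAC extracts, applies case-version
    deduplication and lexicon-based drug-name normalization, assembles
    report-level 2x2 contingency tables against a MedDRA preferred-term event
    set, computes reporting odds ratios with Woolf confidence intervals,
    Fisher exact p-values and Benjamini-Hochberg adjustment, and applies
    staged feasibility and therapeutic-class filters with a full funnel
    audit. A synthetic report generator with planted odds ratios, duplicate
    case versions and messy verbatim drug names makes every stage testable
    without any database download, and calibration studies quantify false
    discovery rate, confidence-interval coverage and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
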