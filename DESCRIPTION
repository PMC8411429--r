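Package: cardioreg
Title: EHR-Based Cardio-Oncology Registry Phenotyping and Care-Gap Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds computational-phenotyping registries of cancer patients
    treated with potentially cardiotoxic therapy from electronic health record
    (EHR) style tables. Provides a SNOMED-style concept-hierarchy engine for
    value-set expansion (include-descendants / AND-NOT rules), a reproducible
    synthetic EHR cohort generator with known ground truth, nested cohort
    construction with attrition accounting, derivation of pre- and
    post-chemotherapy left ventricular ejection fraction (LVEF) care measures,
    rule-based detection of left ventricular dysfunction (LVD) and heart
    failure with reduced ejection fraction (HFrEF), classification of
    guideline-directed medical therapy (GDMT) from active medication lists,
    chart-review validation statistics with exact (Clopper-Pearson) binomial
    confidence intervals, and care-gap reports stratified by cardiology
    referral.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
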