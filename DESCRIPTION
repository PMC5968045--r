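Package: fscreen
Title: Evaluating Colonoscopy Referral Strategies for Sigmoidoscopy-Based
    Colorectal Cancer Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate flexible-sigmoidoscopy (FS) based colorectal
    cancer screening under alternative colonoscopy referral rules. Lesion-level
    colonoscopy findings are classified into the standard neoplasia hierarchy
    (colorectal cancer, advanced adenoma, non-advanced adenoma, hyperplastic
    and other polyps), lesions are split into FS-reachable (distal) and
    proximal under configurable reach assumptions, and twelve referral
    strategies (UK, SCORE, NORCCAP and US/PLCO trial criteria plus guideline
    and threshold-based rules) are applied to each participant's distal
    findings. Outcome measures include sensitivity with exact Clopper-Pearson
    confidence intervals, the number of colonoscopies needed per proximal
    advanced neoplasm detected (NCN), incremental NCN between strategies, and
    negative predictive values, all sex-stratified. A seeded synthetic cohort
    generator calibrated to published screening-colonoscopy marginals makes
    the full pipeline testable without individual-level data, and a
    counts-only mode reproduces published strategy-level results directly from
    aggregate tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
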