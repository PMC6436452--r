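Package: sr2norm
Title: Normative Analysis for the SR2 Rapid Test of Spatial Release from Masking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores progressive-tracking speech-in-speech trials from the SR2
    rapid test of spatial release from masking into target-to-masker-ratio
    (TMR) thresholds, fits age- and hearing-loss-based normative regression
    functions, converts individual scores to Z-scores against those norms, and
    flags abnormal performers. Includes a psychometric listener simulator that
    generates synthetic cohorts with the study's demographic and audiometric
    structure so the entire pipeline can be validated by parameter recovery,
    plus readers and writers for cohort CSVs, trial-level response files, and
    serialized normative models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    broom,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
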