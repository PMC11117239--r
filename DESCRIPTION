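Package: sauronc
Title: Boosting and Survival Analysis of Neoplasia Outcomes in Lizard Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for retrospective veterinary oncology cohorts of lizards:
    harmonized case-record schema with controlled vocabularies and CSV I/O,
    a synthetic cohort generator emulating literature and clinical-registry
    case mixes, componentwise L2 gradient boosting with ridge-penalized
    categorical base-learners, permutation-calibrated per-level significance
    of predictor effects on neoplasia-death versus non-neoplastic outcomes,
    Kaplan-Meier survival contrasts with Greenwood log-log confidence bands,
    and descriptive frequency and survival-time summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
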