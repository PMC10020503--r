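Package: herbsurv
Title: Claims-Based Survival and Co-Prescription Analysis of Herbal Medicine Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for retrospective cohort studies of
    Chinese herbal medicine (CHM) use built on electronic claims data, with
    HIV/AIDS patients developing neurological disease as the motivating
    cohort. Provides a seeded synthetic claims generator with planted
    proportional-hazards effects and co-prescription structure; cohort
    construction from diagnosis, prescription and death tables (case rules,
    exclusion cascade, Charlson comorbidity index, defined daily doses,
    cause-of-death categorisation); propensity-score estimation and 1:2
    caliper matching; Kaplan-Meier, log-rank and Cox proportional-hazards
    estimation implemented from first principles with Efron tie handling;
    and association-rule mining of co-prescription pairs (support,
    confidence, lift) with network cluster detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    tibble,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
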