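Package: psnet
Title: Patient-Sharing Physician Networks and Cancer Treatment Delay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for claims-based patient-sharing physician network
    analysis of cancer treatment delay. Builds weighted physician networks
    from encounter streams, computes the linchpin score (local scarcity of
    a specialty) and care density (care-team familiarity) exposure
    measures, applies a breast-cancer study-cohort inclusion/exclusion
    cascade, and fits hierarchical logistic regressions with
    cross-classified random intercepts for physician and hospital referral
    region. Includes a synthetic claims generator with planted
    exposure-outcome effects so the full pipeline can be exercised and
    validated by parameter recovery without access to restricted claims
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    igraph,
    Matrix,
    lme4,
    jsonlite,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
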