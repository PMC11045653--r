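Package: propmort
Title: Stage-Specific Proportional Mortality for Cancer Registry Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies causes of death among cancer registry cases into
    index cancer, non-index cancer, and non-cancer causes; follows the
    entire cohort until death by observation or extrapolation by
    fractionally allocating causes of death to censored cases; tabulates
    stage-specific cause-of-death distributions by cancer type and
    demographic strata; and computes counterfactual stage-shift scenarios
    for the expected reduction in index-cancer deaths under earlier
    detection. Includes a seeded synthetic registry cohort generator with
    cause-specific yearly hazards, a statistical-cure plateau, and a
    latent-truth side channel for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
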