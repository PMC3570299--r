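Package: duoscore
Title: Mother-Offspring Genetic Risk Scores and Mendelian Randomization for
    Glycaemic Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and validation of weighted fasting-glucose and type 2
    diabetes genetic risk scores in mother-offspring duo cohorts, with the
    supporting machinery for a Mendelian randomization analysis of intrauterine
    glucose exposure and child cognitive outcomes: a typed variant catalogue
    with risk-allele orientation and linkage-disequilibrium proxy handling,
    Hardy-Weinberg and allele-frequency quality control, principal components
    for stratification adjustment, single-variant and confounder association
    scans with expected-null accounting, maternal-versus-offspring effect
    regressions, WHO-rule diabetes classification, and a seeded synthetic
    duo-cohort generator (Hardy-Weinberg founders, Mendelian transmission,
    configurable score-to-phenotype effects) so that every pipeline stage is
    testable without access to individual-level cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
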