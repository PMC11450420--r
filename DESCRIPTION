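Package: youthcomplexity
Title: Data-Driven Clinical Complexity Phenotyping for Youth Mental
    Health Episodes of Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies clinical complexity subgroups among episodes of
    care in youth primary mental health services. Maps routinely
    collected visit-level measures (K10 psychological distress, SOFAS
    functioning, MyLifeTracker quality of life, illness stage, diagnoses,
    presenting issues and psychosocial flags) onto 13 binary complexity
    indicators, imputes missing indicators by chained logistic
    equations, clusters episodes with k-means consensus clustering
    integrated over the imputations, estimates pooled tetrachoric
    correlation networks with multidimensional-scaling layouts, and fits
    multinomial logistic regressions of cluster membership on
    demographic risk factors pooled by Rubin's rules. Includes a seeded
    synthetic cohort generator emulating a youth mental health minimum
    data set with planted cluster structure, so the full pipeline is
    testable without confidential service data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
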