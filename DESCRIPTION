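Package: resistm
Title: Gene-Signature Scoring and Survival Stratification for Colorectal
    Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores bulk-expression cohorts with the two-arm nine-gene
    RESIST-M signature (SERPINE1/SMARCD3 up, seven cholesterol-biosynthesis
    genes down) and four published comparator signatures, dichotomizes risk
    by a median split, and quantifies survival separation with Kaplan-Meier
    curves, the log-rank test, and Cox proportional-hazards ratios.
    Includes per-subtype score comparisons (Wilcoxon rank-sum), a Fisher
    exact test for enrichment of signature-high patients in the
    CMS4/iCMS3-fibrotic subtype, a z-scored heatmap table builder, GMT
    import/export, and a seeded synthetic expression-survival cohort
    generator so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
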