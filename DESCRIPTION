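Package: temporient
Title: Temporal-Orientation Response Analysis with Regional Cerebral
    Blood Flow Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for nine-point temporal-orientation
    ("A-series") questionnaire responses in Alzheimer's disease, mild
    cognitive impairment and non-demented controls. Computes the
    non-demented standard response per sentence, fits a per-participant
    regression line constrained through the "present" pivot (5, 5),
    clusters the resulting (slope, determination-coefficient) features
    with a Gaussian mixture model selected by mean silhouette, screens
    24 arterial cerebral-blood-flow territories with a
    Bonferroni-corrected one-way ANOVA, and exhaustively searches single
    regions and all region pairs with leave-one-out linear discriminant
    analysis. Also provides Patlak graphical analysis of dynamic
    time-activity curves (influx constant K1, distribution volume V0),
    area-weighted ROI-to-territory aggregation, and a seeded synthetic
    cohort generator so every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mclust,
    cluster,
    withr
Config/testthat/edition: 3
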