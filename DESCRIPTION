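Package: saltol
Title: Germination-Stage Salt-Tolerance Screening from Multi-Trait Retention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens germplasm collections for salt tolerance at the seed
    germination stage. From daily germination counts and seedling biomass under
    control and salt treatments it computes germination traits (rate, potential,
    index, vigor index), trait retention ratios under stress, and a composite
    Salt Tolerance Score (STS) obtained by averaging column-standardized
    retention values. Downstream analyses include bootstrap assessment of
    ranking stability (Top-K hit rates), PCA plus K-means tolerance typing,
    trait and cross-environment correlation structure, canonical correlation of
    control and stress phenotype spaces, Isolation Forest anomaly flagging,
    random-forest discrimination of score extremes with ROC/AUC and Gini and
    permutation importances, paired and Welch contrasts with effect sizes, and
    relative-expression analysis of qRT-PCR validation panels by the delta-delta-Ct
    method. A seeded synthetic cohort generator reproduces the statistical
    structure the pipeline assumes so every stage is testable without
    laboratory data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
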