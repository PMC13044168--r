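# saltol

Germination-stage salt-tolerance screening for germplasm collections, built
around a composite **Salt Tolerance Score (STS)** computed from multi-trait
retention under stress.

## The problem

Screening a collection (e.g. 100 sorghum accessions) for salt tolerance at
germination usually compares single traits — final germination rate, early
germination potential — between a control (CK, 0 mM NaCl) and a salt
treatment (here NaCl150, 150 mM NaCl). Single-trait comparisons are noisy and
confounded by baseline vigor: an accession that germinates poorly even in
water looks "sensitive" under any stress. `saltol` implements a multi-trait,
baseline-free alternative:

1. **Traits** from daily germination counts and seedling biomass, per
   replicate dish:
   - germination rate `GR = 100 · N_g / N_t`
   - germination potential `GP = 100 · N_{g,d} / N_t` at an early day *d*
     (default day 3)
   - germination index `GI = Σ_i G_i / D_i` (G_i seeds newly germinated on
     day i)
   - vigor index `VI = GI · W`, with `W` the mean per-plant biomass (g)
2. **Retention** per accession and trait, `R = Trait_NaCl150 / Trait_CK`,
   with the log2 response-spectrum view `log2R` and the relative decline
   rate `RD = 1 − R`.
3. **STS**: each retention column is Z-score standardized; the STS of an
   accession is the mean of its standardized retentions. Higher = more
   tolerant; ranking the STS orders the collection.
4. **Downstream**: bootstrap Top-K hit rates for ranking stability; PCA +
   K-means (k = 3) tolerance typing; trait and cross-environment correlation
   structure; canonical correlation of CK vs stress phenotype spaces;
   Isolation Forest anomaly flagging in log2R space; random-forest
   discrimination of the STS extremes with ROC/AUC, Gini and permutation
   importances; paired/Welch contrasts with effect sizes; and 2^-ΔΔCt
   relative expression for qRT-PCR validation panels.

A seeded synthetic cohort generator (`simulate_cohort()`,
`simulate_ct_table()`) reproduces the statistical structure the analysis
assumes — a latent tolerance multiplier τ acting on daily germination
hazards and biomass — so the whole pipeline is testable without laboratory
data and the score can be validated against known ground truth.

## Worked example

```r
library(saltol)

cohort <- simulate_cohort(cohort_config(rng_seed = 42))   # 100 accessions
traits <- build_trait_table(cohort$germination, cohort$biomass)
fit    <- sts(build_retention_matrix(traits))
fit
#> Salt Tolerance Score (mean of column-Z-scored trait retentions)
#>   100 accessions, 24 trait columns
#>   most tolerant: ACC028 (1.959), ACC062 (1.827), ACC044 (1.489), ACC046 (1.442), ACC030 (1.441)

# does the score recover the latent tolerance the generator planted?
cor(cohort$truth$tau[match(names(coef(fit)), cohort$truth$accession)],
    coef(fit), method = "spearman")
#> [1] 0.970129

extremes   <- select_extremes(fit, q = 0.20)      # 20 + 20 accessions
classifier <- classify_extremes(fit, extremes, seed = 7)
classifier
#> Random-forest discrimination of STS extremes
#>   held-out AUC 1.000 (OOB 1.000), 500 trees, 5 folds
#>   top traits by Gini importance: VI_mean 0.072, GR_mean 0.068, GR_1 0.064

stability <- bootstrap_topk(fit, B = 1000, K = 20, seed = 3)
typing    <- pca_typing(fit, seed = 5)            # tolerant / intermediate / sensitive
```

The held-out AUC of 1.000 says the 20 most and 20 least tolerant accessions
are cleanly separable in multi-trait retention space — expected, since the
labels are thresholded from a score built on the same features; it validates
the internal consistency of the screen, not out-of-sample prediction. The
Spearman correlation of 0.97 against the latent τ is the real parameter-
recovery check. `run_pipeline()` chains every stage and writes one CSV per
result plus a JSON run manifest.

## Documentation

The methods vignette (`vignettes/salt-tolerance-screening.Rmd`) describes
the model, the generator's assumptions, every tunable parameter, and the
design decisions; function-level documentation is in the roxygen comments.
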