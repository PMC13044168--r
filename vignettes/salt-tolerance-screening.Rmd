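---
title: "Multi-trait salt-tolerance screening at germination: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait salt-tolerance screening at germination: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltol)
```

## The screening model

Salt tolerance at the germination stage is a quantitative, multi-trait
property. A single index such as final germination rate confounds two very
different things: how vigorous an accession is in the first place, and how
well it *maintains* that vigor under stress. `saltol` separates the two by
working on trait **retention**,

$$R_{ij} = \frac{\text{Trait}_{ij}^{\text{stress}}}{\text{Trait}_{ij}^{\text{control}}},$$

for accession $i$ and trait $j$. Ratios of an accession to itself cancel
baseline differences; what remains is the proportional response to stress.
The composite **Salt Tolerance Score** is

$$\mathrm{STS}_i = \frac{1}{p}\sum_{j=1}^{p} z_{ij}, \qquad
  z_{ij} = \frac{R_{ij} - \bar R_j}{s_j},$$

the row mean of column-standardized retentions (sample sd, denominator
$n-1$). Standardization makes traits with different dispersions commensurate
and makes the score invariant to any affine rescaling of a raw trait — a
property the test suite checks directly. Averaging many correlated
retentions damps the measurement noise any single trait carries; the
bootstrap module quantifies how much of the final ranking survives
perturbations of the trait panel.

The underlying traits follow the standard germination-assay definitions:
germination rate $GR = 100\,N_g/N_t$; germination potential
$GP = 100\,N_{g,d}/N_t$ at an early census day $d$; germination index
$GI = \sum_i G_i / D_i$ with $G_i$ the seeds newly germinated on day $i$
(1-based days, so day-1 germination carries full weight and $GI$ equals the
seed count when everything germinates on day 1); and vigor index
$VI = GI \times W$ with $W$ the mean per-plant biomass in grams. Per-plant
fresh and dry weight enter the trait panel in their own right as well.

## Trait layout and naming

`build_trait_table()` emits each trait once per replicate (`GI_1`, `GI_2`,
`GI_3`) plus the replicate mean (`GI_mean`), and the retention matrix keeps
this layout as separate columns. Two reasons. First, replicate-suffixed
trait panels are how germination screens are commonly reported, and the
replicate columns carry genuine information about within-accession
consistency. Second, the layout produces a panel of highly correlated
columns, which is precisely the redundancy regime in which a composite
score is robust and in which permutation importance of any single feature
collapses toward zero — a behaviour the classification module demonstrates.
Whether numeric suffixes in such panels denote replicates or census days is
a genuine ambiguity in the field's labelling conventions; we adopt the
replicate reading (the coexistence of a separate `_mean` column supports
it) and provide `replicate_suffix = FALSE` to collapse to means-only panels
for users who prefer the other convention.

Defaults worth knowing: `gp_day = 3` (germination potential is an *early*
percentage; day 3 of a 7-day assay), `vi_weight_basis = "fresh"` (dry weight
is available via one argument), percent traits always on the 0–100 scale.

## Conventions for degenerate cells

Ratio matrices need explicit conventions at zero:

- $R$ with both values zero is 1 (“no change”); a zero control with a
  positive stress value is recorded missing rather than infinite, so a
  single pathological cell cannot dominate a z-scored column.
- $\log_2 R$ at $R = 0$ is missing, not floored at an epsilon.
- Constant retention columns z-score to all zeros rather than NaN; in the
  exact no-stress-effect limit every column is constant, every score is 0,
  and the score spread is exactly zero.
- The STS of an accession with missing cells is the mean of its available
  z-values (no imputation); accessions missing a whole treatment are
  excluded with a warning. Only the PCA/K-means, Isolation Forest and
  CCA steps — which need complete rows — use per-column median imputation,
  confined to those steps.
- Ranks are descending in STS with ties broken by accession label, so a
  re-run can never reorder equal scores.

## The synthetic cohort generator

`simulate_cohort()` defines the study conditions every test and acceptance
check runs under: **100 accessions × 2 treatments (CK, NaCl150) × 3
biological replicates × 7 daily censuses of 50-seed dishes**. Germination is
a discrete-time hazard process — each remaining seed germinates on day $d$
with probability $h_d$, binomially sampled per dish. Only the daily count
vector is observable in a real assay, so any generative process with
configurable daily probabilities would do; hazards were chosen because they
compose naturally with a multiplicative stress effect.

Each accession carries a latent tolerance multiplier $\tau \in (0,1]$; under
stress the daily hazards and biomass means are multiplied by $\tau$. This
makes every expected trait retention monotone in $\tau$ — the ratio-scale
structure the STS assumes — and gives the tests a ground truth: at default
noise the Spearman correlation between $\tau$ and the STS must be at least
0.9, and in the noise-free limit the two orderings coincide exactly.

Class structure follows the view that tolerance is a continuous gradient
rather than a dichotomy: accessions are assigned to tolerant / intermediate
/ sensitive classes with proportions 0.25 / 0.50 / 0.25 and $\tau$ drawn
uniformly within contiguous class ranges 0.75–0.95 / 0.50–0.75 / 0.20–0.50,
i.e. thresholds on one continuous scale. Remaining defaults are free
parameters a germination lab would recognise as realistic rather than
published values: CK daily hazards `c(0.02, 0.15, 0.35, 0.30, 0.20, 0.10,
0.05)` (a mid-week germination peak, ~77% final CK germination), fresh
weight 0.05 g and dry weight 0.008 g per plant, biomass CV 10%. Replicate
variance and seeds-per-dish are likewise unreported quantities in typical
screens; 50 seeds and binomial counting noise are conventional. `noise`
has a sharp semantic: `count = 0` switches to deterministic expected
(fractional) counts so noise-free limits are well defined; any positive
value means binomial draws.

The Ct-table generator (`simulate_ct_table()`) produces the validation
panel: 8 genes in three categories, with stress shifting the target Ct by
$-\log_2(\text{fold change})$ for the accession's class — ion-transport
genes 3.0× in tolerant vs 1.3× in sensitive accessions, a core response
gene 2.5× vs 1.2×, transcription factors down-regulated (0.4× vs 0.8×,
i.e. lower in tolerant accessions) — Gaussian noise of 0.2 cycles in Ct
space, and a treatment-invariant reference gene. Intermediate-class
accessions, if sampled, get the geometric mean of the two fold changes.

What the generator does **not** emulate: dormancy and hard-seededness,
fungal losses, day-to-day chamber drift, correlated replicate effects,
non-multiplicative (e.g. threshold) stress responses, and any physiological
endpoints (MDA, SOD, proline, Na⁺/K⁺). Passing tests therefore demonstrate
that the pipeline's statistics behave as designed under the assumed
structure, not that a particular real collection will separate as cleanly.

## Stability, typing, classification

**Bootstrap Top-K hit rates.** Each of B = 1000 iterations resamples the
standardized trait *columns* with replacement and re-ranks accessions by the
row-mean score; an accession's hit rate is the fraction of iterations it
lands in the Top K (= 20). Columns are the resampling unit because the
question is robustness to the trait panel; `resample = "accessions"` is
available for the cohort-perturbation question. Resampled columns are
reused as-is since z-scoring is idempotent per column. Complete data obeys
the counting identity $\sum_i \text{hit}_i = K$, which the tests assert
exactly.

**PCA + K-means typing.** PCA on the standardized retention matrix; PC1's
sign is oriented to correlate positively with the STS, so "tolerant
accessions score higher on PC1" holds by construction rather than by the
luck of an eigenvector sign. K-means (k = 3, 10 seeded restarts) runs on
the first two PC scores, and clusters are named tolerant / intermediate /
sensitive by descending mean STS — a mapping invariant to K-means' internal
label permutation.

**Random-forest discrimination.** Labels are the upper and lower STS
quantiles (default q = 0.20; q = 0.05 mirrors a 5 + 5 qRT-PCR panel);
features are the same standardized retention columns. Because the labels
are thresholded from a function of the features, a held-out AUC near 1.000
is the expected outcome and is reported as an internal-consistency check of
the multi-trait space, not as generalisation. We still evaluate on
stratified 5-fold cross-validated probabilities rather than training scores
— an in-sample AUC would be uninformative even as a consistency check — and
report the out-of-bag AUC alongside. Forest settings: 500 trees, default
feature-subset rule, seeded. AUC uses the Mann–Whitney rank formula (ties
half-weighted); Gini importance is the forest's normalized mean impurity
decrease; permutation importance is the mean held-out-AUC drop over
within-column shuffles, scored on AUC for threshold independence.

**CCA.** Canonical correlations between the CK and stress trait spaces are
the singular values of $S_{xx}^{-1/2} S_{xy} S_{yy}^{-1/2}$ after column
standardization, with a ridge (default $10^{-8}$) on the within-set
covariances because replicate-suffixed panels are nearly collinear;
near-constant columns are dropped and components are capped at
$\min(p_x, p_y, n-1)$ with a warning.

**Isolation Forest.** Implemented in the package (100 trees, subsample
≤ 256, score $2^{-E[h]/c(\psi)}$), operating in log2R space where
response-pattern outliers are additive; the $\lceil \text{contamination}
\cdot n\rceil$ highest scores are flagged.

## Contrast statistics and expression

Within-accession CK-vs-stress contrasts use paired t-tests with Cohen's
$d_z$ (mean difference over sd of differences — the natural paired effect
size, and the one a volcano-style effect/significance screen wants);
between-group contrasts use Welch's t-test with fractional
Welch–Satterthwaite df. Zero-variance inputs return flagged degenerate
results (p = 1 for identical arms) instead of NaN. The trait screen ranks
traits by $(|d_z|, -\log_{10} p)$ and applies no multiplicity correction by
default, reflecting standard practice for descriptive screens;
Benjamini–Hochberg q-values are one argument away.

Relative expression is $2^{-\Delta\Delta Ct}$ with the calibrator taken as
the *mean* control $\Delta Ct$ of the accession-gene — so control
replicates scatter around 1 with geometric mean exactly 1, an identity the
acceptance suite checks to machine precision. Technical replicates are
averaged in Ct space before $\Delta Ct$; statistics run on $\log_2$ relative
expression, which equals $-\Delta\Delta Ct$ exactly, so either scale gives
identical tests. Amplification-efficiency correction is out of scope.

## Numerical and reproducibility choices

- Every stochastic stage takes an explicit integer seed; `run_pipeline()`
  derives one per stage from its master seed, and seeded functions restore
  the caller's RNG state. Two runs with equal inputs and seed produce
  byte-identical output files.
- Sample sd (ddof = 1) throughout; fractional Welch df left fractional.
- Problem sizes used by the test and acceptance suites — the default
  100-accession cohort, B = 1000 bootstrap iterations, 1000 null screens of
  20-accession cohorts for the type-I calibration, 100-instance oracle
  sweeps — were chosen as the smallest sizes at which the checked
  identities and Monte-Carlo bounds are sharp.

## Known limitations

The score weights all retained trait columns equally; strongly redundant
panels effectively up-weight their module (here: the germination-dynamics
block), which matches the screening intent but is a modelling choice, not
an inference. Retention is undefined for accessions that fail completely
under control conditions. The classifier's AUC must not be read as
predictive performance on unlabeled germplasm. And all quantitative
guarantees in the test suite are statements about the generator's
assumptions — multiplicative stress action, independent binomial counting
noise — not about any particular field population.
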