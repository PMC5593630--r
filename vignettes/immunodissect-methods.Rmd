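---
title: "Methods: marker derivation, infiltration scoring, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker derivation, infiltration scoring, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunodissect)
```

# The problem

Bulk tumor expression profiles are mixtures: part tumor cell program, part
stroma, part infiltrating immune cells. In breast cancer the degree of
lymphocytic infiltration carries prognostic information, particularly in
estrogen-receptor-negative (ER-) disease, but direct measurement
(pathologist grading of stained sections, flow cytometry) is not available
for most archived cohorts. `immunodissect` estimates lymphocyte infiltration
directly from expression, in two stages:

1. **Marker derivation.** Starting from small, tiered sets of known
   cell-type genes, an iterative semi-supervised linear classifier expands
   them into genome-wide rankings of cell-type specificity against a large
   blood expression compendium, and the top 100 genes per cell type (B cell,
   CD8+ cytotoxic T lymphocyte, Th1, Th2) become that cell type's signature.
2. **Scoring.** Any cohort, z-score transformed per gene, is scored per
   sample by averaging the z-scores of a signature's genes. The same
   averaging applied to an ER-associated gene set gives an ER activity
   score whose sign encodes the ER+/ER- call.

An accompanying statistical suite runs the analyses such scores are used
for: trends across ordinal infiltration grades, group comparisons by ER
status, molecular subtype, and genomic instability (CAAI), robustness of the
trends to marker-gene dropout, quartile-stratified Kaplan-Meier survival,
and paired pre/post-treatment comparisons.

# The z-score and the signature score

For gene $g$ and sample $s$ with normalized intensity $x_{gs}$,

$$z_{gs} = \frac{x_{gs} - \mu_g}{\sigma_g},$$

where $\mu_g, \sigma_g$ are the mean and standard deviation of $g$ across
all samples of the cohort. Two conventions are deliberate:

* $\sigma_g$ uses the sample (n−1) denominator, the default of mainstream
  statistics environments.
* Genes with $\sigma_g = 0$ are **dropped**, not set to $z = 0$: a constant
  gene carries no signal, and imputing zeros would dilute averaged scores
  toward zero differently in different cohorts.

The infiltration score of sample $s$ for a signature of $n$ genes is the
plain average $d_s = \tfrac1n \sum_{i} z_{is}$ over the signature genes
**present in the matrix** — genes not assayed on a platform are excluded and
$n$ adjusted, which is also what makes the dropout-robustness question
meaningful. The total lymphocyte score deduplicates the union of the four
signatures before averaging, so a gene shared by two signatures counts
once. ER calls use strict inequalities (score < 0 is ER-, > 0 is ER+); an
exact 0 is left uncalled rather than forced into a class.

# Marker derivation

## Tiered standards

For each cell type, genes unique to that type's input list are high-tier
positives; genes shared with another type (in practice the Th1/Th2 overlap)
are low-tier positives; the other types' unique genes are the negatives.
Low-tier positives are never used as negatives.

## The iterative classifier

Genes are instances; a gene's feature vector is its z-scored expression
profile across the compendium samples. Each round:

1. fit a ridge-regularized linear discriminant (least squares on ±1 labels,
   solved in closed form) with the current positives (initially the high
   tier only) against the negatives;
2. score every compendium gene by its signed distance to the decision
   boundary;
3. promote low-tier positives scoring at or above the low tier's median
   score (`promotion_threshold = 0.5`) into the training positives —
   promotion is monotone, membership is never revoked;
4. stop when the promoted set stabilises, or after `max_iterations` (10)
   with a warning.

The final scores rank all genes; `top_n = 100` genes form the signature,
with boundary ties broken lexicographically by gene symbol so selection is
deterministic. Training genes remain eligible for the ranking but are
flagged in the output.

Two design choices deserve justification. The classifier is *linear* so
that in the noiseless limit the planted-program separation is exact — this
is a tested invariant, and any margin-based regularized linear model would
satisfy the contract (the deliverable is the ranked score, not
coefficients). The closed-form solve (rather than an iterative fitter) makes
the ranking exactly reproducible and invariant to sample-column permutation
up to float rounding, which iterative coordinate-descent solvers do not
guarantee at their default tolerances. The original published procedure
describes iterative selection of the best standard set without specifying
internals; the train → score → promote → retrain loop here is this package's
concrete interpretation of that scheme. A co-expression-based reduction of
the ranked list is mentioned in the source method but unspecified; we select
the plain top 100 and note the omission.

## Cross-validation

`crossval_auc()` assigns standard genes to 5 folds, stratified separately
over high positives, low positives, and negatives so every fold holds out
both tiers. The entire iterative procedure runs inside each training fold;
held-out standard genes (both positive tiers vs negatives) are scored by the
resulting discriminant and summarized as AUROC via the rank (Mann-Whitney)
identity.

# Statistics

* **Rank sum** (two unpaired groups): exact two-sided p by full enumeration
  of the permutation distribution of the rank sum when both groups have ≤ 10
  samples (ties handled; the distribution is symmetric, so the tail rule
  equals the usual doubling), otherwise the normal approximation with tie
  and continuity correction.
* **Signed rank** (paired): pairs keyed by patient identifier; unmatched
  patients are an error, all-zero differences return p = 1 with a warning.
* **ANOVA across infiltration grades**: one-way. The source describes a
  "two-way ANOVA" but every reported comparison is single-factor; we
  implement the single factor actually used.
* **Ordinal trend**: Kendall tau-b (tie-corrected) between scores and
  category ranks, with the tie-corrected normal-approximation p-value —
  category variables are heavily tied, so tau-a would be misleading.
* **Pearson correlation** with the two-sided t-transform p.
* **Quartile stratification**: "high" strictly above the type-7
  (linear-interpolation) 75th percentile; threshold ties go to "low" so
  "high" is exactly the upper tail.
* **Survival**: product-limit curves and the two-group 1-df log-rank test
  via the `survival` package, applied within ER strata to the high/low
  quartile groups. Groups with zero events are flagged unreliable. Survival
  here is generic time-to-event; whether the original cohort endpoint was
  overall or disease-specific survival is not modelled.
* p-values are reported unadjusted, matching per-test reporting in the
  source analyses; a Bonferroni option exists on the suite.

## Dropout robustness

`robustness_analysis()` removes `round(f·n)` signature genes (at least one
for f > 0) without replacement, recomputes the score, and tests the Kendall
trend against the infiltration categories; the default grid is 0–0.95 in
0.05 steps with 50 repetitions per fraction. The summary
`max_preserved_fraction` is the largest grid fraction at which **all**
repetitions stay significant at 0.05. Because the published description is
ambiguous between removing a fraction per step and removing a fixed 50 genes
50 times, both modes are exposed (`fractions` vs `remove_counts`); fraction
mode is the default.

# The synthetic benchmark

The generators exist to give every downstream stage a ground truth; their
defaults are the package's fixed study conditions, not tuning knobs.

## Blood compendium

400 samples × 4000 genes of unit Gaussian log-intensity-like noise. Five
programs of 120 genes (B cell, CTL, Th1, Th2, monocyte); the two T-helper
programs share 30 genes, no other overlap. Each cell type is active in a
sample with probability 0.3, adding 2.0 to its program genes there — a
moderate effect against noise sd 1.0. Standards are built from 40 seed genes
per type; shared Th1/Th2 seeds are drawn once and enter both lists, so the
tier structure (unique → high, shared → low) is consistent by construction.

## Tumor cohort

300 cross-sectional samples plus 29 ER+ patient pairs (58 biopsies,
pre/day-90, mirroring the size of the aromatase-inhibitor cohort analysed in
the source study). Per sample, a latent ER activity $a_s \sim N(0,1)$
(ER+ iff $a_s$ exceeds the 24%-quantile threshold, giving the METABRIC-like
76% ER+ share) and a shared latent infiltration factor $u_s \sim N(0,1)$.
Each cell type's true fraction is Beta-distributed (concentration 80) around

$$m_c(s) = 0.15 + 0.12\,u_s - 0.06\,a_s,$$

clamped to [0.01, 0.9]. The *shared* factor is essential: with independent
per-type noise, no slope can simultaneously give per-signature ER
comparisons adequate power at n = 300 (24% ER-) and keep the planted
ER/total-infiltration correlation near the intended r ≈ −0.4, because
averaging four independent types inflates |r| above 0.6 at any slope with
per-type power. With the shared factor the defaults give r in roughly
[−0.49, −0.29] across seeds (mean ≈ −0.41). CAAI+ samples (15%) have all
fractions halved. Expression adds the ER program (50 genes, scaled by
$a_s$) and each signature's program (scaled by 8 × its fraction) to unit
noise.

Survival is exponential with log-hazard $b_0 + b_1 f_s^{tot}$,
$b_0 = \log 0.1$, $b_1 = -1.5$ in ER- and $0$ in ER+, under independent
exponential censoring at rate $0.1\,e^{b_0}$ (roughly 20% censored). These
dispersion and censoring values were fixed by a power analysis run on the
generator alone — the planted ER, CAAI, treatment, and ER—survival effects
must be recoverable by the suite with ≥ 0.9 probability while null
configurations (flat hazard, shuffled labels) stay at the nominal 5%
rejection rate — and are not revisited.

Infiltration categories are quartile cuts (0.25/0.5/0.75) of the
cross-sectional total fraction, giving balanced "absent/mild/moderate/
severe" grades; real pathologist grading has no stated mapping to
fractions, so balance is a convention, not an estimate.

## What passing tests do and do not show

The generator plants clean monotone structure: Gaussian noise, no batch or
probe effects, no correlation between immune programs and unrelated genes,
and a category variable derived exactly from the quantity the scores
estimate. Recovery under these conditions demonstrates the machinery is
correct and calibrated — not that real cohorts, with H&E grading noise,
platform differences, and non-lymphocyte stromal admixture, will reproduce
the same effect sizes. Published cohort-level numbers (per-cell-type AUCs,
tau values, cohort p-values) depend on controlled-access data and are not
recomputable here; the tests instead check the bounds those numbers imply
(CV AUROC ≥ 0.7 per cell type; trends preserved at 50% gene loss) on the
synthetic conditions.

# Problem sizes and runtime

Test and acceptance runs use the default 400 × 4000 compendium and
300(+58) × 4000 cohort; multi-seed meta-tests (null calibration,
correlation-band checks) use a reduced 700-gene universe with the same
planted structure, which leaves the tested statistics' calibration
unchanged while keeping 50-seed loops cheap. The acceptance sweep evaluates
19 removal fractions × 50 repetitions × 4 signatures.

# Known limitations

* The iterative promotion scheme is an interpretation of a published method
  whose internals are not restated in the source; with no low-tier
  positives it reduces to a single supervised fit (a tested property).
* Whether training genes may appear in a published signature is unstated;
  here they are eligible and flagged.
* The ER activity sign rule calls roughly half of a symmetric cohort ER-;
  on the synthetic cohort (76% ER+) the planted label and the sign-rule
  call therefore disagree for mid-range samples, and the suite uses the
  annotated label, keeping the sign rule as a separate, tested operation.
* Only two-group log-rank is provided; multi-group subtype survival is out
  of scope.
* No single-sample GSEA-style alternatives to the averaging score, no GO
  enrichment, and no deconvolution-method comparison.
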