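# immunodissect

Estimating tumor-infiltrating lymphocyte levels from bulk expression data,
and deriving the marker gene signatures that make that possible.

Bulk tumor expression profiles mix tumor, stromal, and immune transcripts.
`immunodissect` is for researchers who want to quantify B cell, cytotoxic T
lymphocyte (CTL), Th1, and Th2 infiltration in archived expression cohorts
where no direct measurement (pathology grading, flow cytometry) exists, and
to relate those estimates to estrogen receptor (ER) status, molecular
subtype, genomic instability (CAAI), treatment, and survival.

## What it computes

**Marker derivation.** Starting from tiered standards — high-confidence
positives (genes unique to one cell type), low-confidence positives (genes
shared with a related type), and negatives (other types' unique genes) — an
iterative semi-supervised ridge linear discriminant ranks every gene of a
blood expression compendium by cell-type specificity (genes are instances;
a gene's features are its expression profile across compendium samples).
Each round promotes low-tier positives scoring above the low tier's median
into the training set and refits, until the promoted set stabilises. The
top 100 genes form the cell type's signature, and 5-fold cross-validation
on held-out standard genes reports AUROC.

**Scoring.** With per-gene z-scores
`z_gs = (x_gs − μ_g) / σ_g`, the infiltration score of sample *s* for an
*n*-gene signature is the average `d_s = (1/n) Σ_i z_is` over signature
genes present in the matrix (missing genes are excluded and *n* adjusted).
The total lymphocyte score averages over the deduplicated union of the four
signatures; the same formula on an ER-associated gene set gives an ER
activity score whose sign (strictly <0 / >0) calls ER−/ER+.

**Statistics.** Wilcoxon rank-sum (exact by enumeration when both groups
≤ 10), Wilcoxon signed-rank for paired timepoints, one-way ANOVA and
Kendall tau-b trends across ordinal infiltration grades, Pearson
correlations, gene-dropout robustness of the tau trend, and
quartile-stratified Kaplan–Meier / log-rank survival within ER strata.

**Synthetic benchmark.** `generate_compendium()` and
`generate_tumor_cohort()` plant all of the above structure (cell-type
programs, ER-anticorrelated infiltration fractions, CAAI reduction,
ER−-only survival benefit, post-treatment uplift) with known ground truth,
so the whole pipeline is testable end to end. See the methods vignette
(`vignettes/immunodissect-methods.Rmd`) for the model and every default.

## Worked example

```r
library(immunodissect)

# 1. synthetic blood compendium with planted programs, tiered standards
comp <- generate_compendium(compendium_config(seed = 101))
z    <- zscore_transform(comp$expression)

# 2. derive signatures and cross-validate
cv <- crossval_auc(z, comp$standards$CTL, derivation_params(seed = 101))
sprintf("CTL mean 5-fold AUROC: %.3f", cv$mean_auc)
#> "CTL mean 5-fold AUROC: 1.000"

markers    <- lapply(comp$standards[c("Bcell","CTL","Th1","Th2")],
                     nanodissect, compendium = z,
                     params = derivation_params(seed = 101))
signatures <- lapply(markers, `[[`, "signature")   # 100 genes each

# 3. score a synthetic tumor cohort and run the associations
coh <- generate_tumor_cohort(tumor_cohort_config(seed = 202), signatures)
zt  <- zscore_transform(coh$expression)
st  <- score_table(zt, signatures, er_signature = coh$er_genes)
ann <- coh$annotations
cross <- ann$timepoint == "none"

compare_groups(st$total[cross],
               factor(ann$er_status[cross], levels = c("ER+", "ER-")),
               "rank_sum")
#> rank_sum: statistic = 4323, p = 2.63e-08 (n = 233/67)

ordinal_trend(st$total[cross], ann$infiltration_category[cross])
#> kendall_tau_b: statistic = 0.8634, p = 6.83e-89 (n = 300)

correlate(st$er_activity[cross], st$total[cross])
#> pearson: statistic = -0.4172, p = 4.58e-14 (n = 300)

sel <- cross & ann$er_status == "ER-"
km_logrank(ann$survival_time[sel], ann$event[sel],
           quartile_stratify(st$total[sel]))
#> Log-rank low vs high: chisq = 12.38, p = 0.000434 (n = 50/17, events = 45/7)
```

Reading the output: ER− tumors score higher for total lymphocyte
infiltration than ER+ (positive direction, rank-sum p ≈ 3e−8); scores rise
monotonically across the planted absent→severe grades (tau-b 0.86); ER
activity anti-correlates with infiltration (r ≈ −0.42); and in the ER−
stratum the upper-quartile ("high") group has markedly fewer events (7/17
vs 45/50, log-rank p ≈ 4e−4) — all matching the structure the generator
planted. `run_association_suite(st, ann)` produces the full
machine-readable report, and `run_pipeline(pipeline_config(seed = 1))`
executes every stage into a run directory with a reproducibility manifest.

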