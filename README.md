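# riskgrader

Grading autism spectrum disorder (ASD) severity from annotated exome
variants. The package is aimed at researchers who have a multi-sample,
annotation-bearing VCF (gene symbol, SIFT and PolyPhen labels, optionally a
population allele frequency) and a per-sample clinical severity table, and
who want two complementary analyses:

1. **Polygenic risk classification.** Per-variant allelic odds-ratio
   association between severe and mild samples (the 2×2 allele-count
   cross-product `OR = ad/bc`, Pearson χ² ranking, Haldane–Anscombe
   correction for zero cells), top-*k* feature selection nested inside
   every fold of a leave-one-out cross-validation, and a Cauchy-prior
   regularized logistic risk model (the `bayesglm` model: standardized
   predictors, prior scales 2.5 / 10, approximate-EM penalized IRLS) that
   stays finite on separable folds. Performance is reported as accuracy,
   sensitivity, specificity, Matthews correlation, ROC AUC, and
   reclassification measures (NRI/IDI); out-of-fold risks are clustered
   (UPGMA on the scalar risk) into molecular subtypes with discordance
   flags against the clinical grading.

2. **Important-gene (IG) discovery.** Per sample, genes carrying at least
   one homozygous-alternate variant flagged simultaneously by SIFT
   (`deleterious`, `deleterious_low_confidence`) and PolyPhen
   (`possibly_damaging`, `probably_damaging`); per sub-phenotype group
   ({IQ, memory, attention, verbal} × {severe, mild}), genes present in at
   least n−2 of the group's n members; Venn partition of the eight group
   IG sets (the all-sets region is the severity-independent signature);
   Monte-Carlo multi-set intersection enrichment; and validation against
   external autism gene lists (known vs novel).

A seeded synthetic-cohort generator (`simulate_cohort()`) reproduces the
cohort structure both arms assume — 33 samples split 15 severe / 18 mild,
sub-phenotype margins IQ 15/18, verbal 14/19, attention 24/9, memory
15/18, Hardy–Weinberg genotypes with planted case-enriched risk variants
and planted damaging genes — so the entire pipeline is testable without
patient data.

## Worked example

```r
library(riskgrader)

cohort <- simulate_cohort(cohort_spec(seed = 42, planted_ig_genes = NULL))
scan <- saturation_scan(cohort$genotypes, cohort$annotations,
                        cohort$phenotypes, k_max = 40)
scan
#> Saturation scan over top-k selected variants
#>      6      8     10     12     14     16     18
#> 0.8788 0.8788 0.8788 0.8485 0.8788 0.8485 0.8485
#> chosen k = 6 (accuracy 0.8788)

res <- run_loocv(cohort$genotypes, cohort$annotations, cohort$phenotypes,
                 k = scan$chosen_k)
res
#> LOOCV (k = 6, 33 folds)
#>   accuracy 87.88%  sensitivity 80.00%  specificity 94.44%
#>   MCC 0.759  AUC 0.944  pooled variants 11

cluster_risk_scores(res$per_sample)
#> Risk-score clustering: 33 samples, 4 discordant with clinical grading
#>   discordant: S028, S011, S003, S013
```

Reading: the saturation scan evaluates LOOCV accuracy over a growing number
of fold-selected top variants and stops once accuracy has saturated; here
six variants per fold already classify 29/33 samples correctly out-of-fold
(sensitivity 80% of the 15 severe, specificity 94.4% of the 18 mild,
MCC 0.759, AUC 0.944), and the union of fold selections contains 11 distinct
variants. UPGMA clustering of the out-of-fold risks splits the cohort into
high- and low-risk molecular subtypes; four samples land in the subtype
opposite to their clinical grading.

The IG arm runs off the same inputs:

```r
full <- simulate_cohort(cohort_spec(seed = 42))  # includes planted IG genes
ig <- ig_analysis(full$genotypes, full$annotations, full$phenotypes)
ig$severity_independent
#> [1] "GENE0001"
```

`GENE0001` is the generator's planted all-samples damaging gene — the
synthetic analogue of a severity-independent ASD signature — recovered by
the n−2 commonality rule in all eight sub-phenotype groups.

The same pipelines are scriptable via the installed CLI
(`exec/riskgrader`): `riskgrader simulate|grade|ig|validate --help`.

## Package layout

* `R/cohort.R` — synthetic cohort specification, simulation, writer
* `R/variant_io.R` — annotated VCF and phenotype-table readers
* `R/association.R` — allele tables, odds ratios, ranking, top-k selection
* `R/risk_model.R` — Cauchy-prior logistic fit and prediction methods
* `R/evaluation.R` — LOOCV, saturation scan, metrics, NRI/IDI, clustering
* `R/ig_pipeline.R` — qualifying variants, n−2 IG sets, Venn, enrichment
* `R/genelists.R` — external gene-list loading and validation
* `R/cli.R`, `exec/riskgrader` — command-line entry points
* `vignettes/severity-grading-methods.Rmd` — models, assumptions, choices
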