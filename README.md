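# symptomDE

Dimension-resolved differential expression and alternative-splicing analysis
for continuous symptom phenotypes.

## The problem

Psychiatric symptom scales are not one number. The PCL-17 PTSD checklist, for
example, sums 17 items (each scored 1–5) into a total burden score, but those
items group into four correlated subdimensions — re-experiencing, avoidance,
numbing and hyperarousal — and different transcriptomic signals can track
different subdimensions. A second complication is that gene expression need
not change linearly with symptom burden: thresholds, saturation and U-shaped
dose–response patterns are all plausible.

`symptomDE` implements an analysis pipeline for whole-blood (or any bulk)
RNA-Seq against such a phenotype:

- **Gene level.** Counts are modelled with a negative-binomial generalized
  additive model (NB-GAM),

  `log E[Y_gi] = log s_i + beta_0 + f_g(PCL_i) + covariates_i`,

  where `s_i` is a median-of-ratios size factor and `f_g` a penalized cubic
  B-spline (P-spline, second-order difference penalty) whose smoothing
  parameter and NB dispersion are selected by REML. The penalty null space is
  the linear functions, so the effective degrees of freedom (edf) of the
  fitted smooth measures nonlinearity: edf = 1 is a straight line. Genes with
  Benjamini–Hochberg FDR < 0.05 are differentially expressed; those with
  edf > 1.5 are called nonlinear.
- **Isoform and splicing level.** Isoform `log(TPM + 1)` and per-event
  percent-spliced-in values, `PSI = sum TPM(inclusion) / sum TPM(total)`
  analysed on the log-odds scale `log(PSI/(1-PSI))`, go through the Gaussian
  analogue (penalized-spline regression with an F-type smooth test).
- **Post-hoc curve clustering.** Fitted smooths of significant nonlinear
  genes are clustered with k-medoids (PAM); the number of clusters is chosen
  by the gap statistic against a PCA-aligned uniform reference.
- **Cross-dimension comparison.** Features unique to one subdimension
  (FDR < 0.05 there, p > 0.1 in the other three), −log10 p correlations,
  4-set Venn region counts, significance-threshold curves, and a chi-square
  goodness-of-fit test comparing the event-type mix of significant splicing
  events against the transcriptome-wide background (small expected categories
  merged).
- **Gene-set enrichment.** Preranked GSEA on −log10 p with the weighted
  Kolmogorov–Smirnov running sum, gene-label permutation, NES and
  positive/negative pooled-null FDR; plus a hypergeometric
  over-representation test for dimension-unique gene lists.
- **Synthetic cohorts.** A seeded generator produces PCL-17 item scores from
  a latent correlated model, adjustment covariates, NB counts, isoform TPMs
  and splicing events with planted null / linear / nonlinear phenotype
  effects and full ground truth, so every stage is testable without any
  cohort download.

## Worked example

```r
library(symptomDE)

spec <- cohort_spec(n_subjects = 120, n_genes = 300, seed = 42)
co <- simulate_cohort(spec)

counts <- filter_low_counts(co$counts, min_mean = 5)
sf <- estimate_size_factors(counts)
covars <- co$phenotypes[, c("age", "race", "cd4t", "cd8t", "monocytes",
                            "nk", "bcells", "sv1", "sv2")]
de <- run_de(counts, co$phenotypes$total_pcl, covars, size_factors = sf)
de
#> DE result: 300 features; 65 significant at FDR < 0.05 of which 34 nonlinear (edf > 1.5)

head(subset(de$results, nonlinear), 4)
#>           feature_id  p_value      fdr  edf nonlinear mean_expression
#> gene_0007  gene_0007 0.00e+00 0.000000 3.07      TRUE          264.30
#> gene_0014  gene_0014 0.00e+00 0.000000 2.68      TRUE            9.62
#> gene_0015  gene_0015 0.00e+00 0.000000 4.03      TRUE          100.01
#> gene_0018  gene_0018 2.22e-05 0.000109 2.70      TRUE          407.63

nl <- de$results$feature_id[de$results$nonlinear]
cl <- cluster_curves(de, nl, seed = 1)
cl$gap
#> Gap statistic: optimal k = 6
```

The spec plants 10% linear and 10% nonlinear effects (amplitude 0.4 on the
log scale) among 80% null genes; the run above recovers 65 of the ~60
planted genes plus the expected handful of false positives, and the fitted
curves of the nonlinear calls group into shape clusters (each planted
archetype can appear with either sign, so the clustering sees more than five
patterns). `run_pipeline()` chains all stages — gene, isoform and splicing
analysis for the total score and all four subdimensions, clustering,
comparison tables and GSEA — and writes every table plus a JSON manifest
with checksums; `inst/scripts/run-pipeline.R` is a command-line wrapper
around it driven by a YAML config.

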