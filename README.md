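# reopairs

Rank-based discovery of qualitative serum miRNA biomarkers.

Serum miRNA panels are attractive non-invasive diagnostics, but models
built on absolute intensities are fragile: batch effects, platform
changes and normalisation choices all move the decision thresholds.
`reopairs` implements a discovery pipeline whose every statistic depends
only on *relative expression orderings* (REOs) — whether, within one
sample, miRNA *a* exceeds miRNA *b*. Because any strictly increasing
per-sample distortion preserves all within-sample orderings, the
resulting classifiers apply to a new serum profile directly, with no
normalisation. The package is aimed at computational biologists
building cancer-specific (case versus pooled-other-cancers) serum
classifiers from multi-cohort microarray compendia.

## The statistics at the core

For a pair (a, b) and a group of m samples,
`PCT(E_a > E_b) = k/m` counts the samples ordering a above b. The
pipeline screens:

* **stable pairs** — majority-direction PCT ≥ 80% in controls;
* **reversed pairs** — the 2×2 direction table [[n1, n2], [m1, m2]]
  (control/case) is significant by a two-sided Fisher exact test after
  Benjamini–Hochberg correction (FDR < 5%);
* **candidate pairs** — degree of reversal
  ΔPCT = PCT_control(E_a > E_b) − PCT_case(E_a > E_b), |ΔPCT| ≥ 0.7;
* **differential miRNAs** — hypergeometric upper tail
  P = 1 − Σ_{i=0}^{k−1} C(n, i) C(M−n, N−i) / C(M, N) over a miRNA's
  directional pair memberships (M stable, N reversed pairs), BH across
  miRNAs;
* **the classifier** — a seeded greedy forward selection maximising the
  training geometric mean √(NPV × PPV) of a majority-voting rule over
  candidate pairs, with LASSO→AIC-stepwise regression and a 500-tree
  random forest as comparators, and AUC/ACC/SPE/SEN/NPV/PPV reporting.

Sample QC reproduces the standard serum-compendium steps: k-nearest
neighbour imputation, correlation-based outlier removal per (dataset,
phenotype) stratum (±2 SD), Euclidean duplicate screening (< 1), and a
stratified 70/30 split.

A synthetic cohort generator (`simulateCohort`) plants known pair
reversals in a multi-batch, multi-phenotype cohort — with monotone
batch distortions, missing values, outliers and near-duplicates — so
every stage can be validated against ground truth.

## Worked example

```r
library(reopairs)
design <- simulationDesign(rngSeed = 1L)   # 300 miRNAs; 200 BrC + 600 other-cancer controls
sim    <- simulateCohort(design)
imp    <- imputeKnn(sim$experiment, k = 10L)
res    <- runReoPipeline(imp$experiment, reoConfig(rngSeed = 1L))

head(res$candidates[, c("pair_a","pair_b","pct_control","pct_case","delta_pct","p_adjusted")], 4)
#>         pair_a   pair_b pct_control pct_case delta_pct p_adjusted
#> 13493 miR-0033 miR-0182      0.9571   0.0214     0.936  2.72e-101
#> 6318  miR-0121 miR-0124      0.0429   0.9643    -0.921   8.77e-98
#> 34546 miR-0207 miR-0289      0.0500   0.9714    -0.921   3.76e-97
#> 13441 miR-0149 miR-0181      0.9500   0.0357     0.914   1.97e-95

res$model
#> VotingModel with 4 pairs (seed miR-0033|miR-0182)
#> final training sqrt(NPV x PPV): 1.0000

res$test_metrics[, 1:7]
#>      auc    acc spe    sen    npv ppv gmean_npv_ppv
#> 1 0.9998 0.9958   1 0.9833 0.9945   1        0.9972
```

Reading the output: all four selected pairs are planted ground-truth
reversals (`plantedPairs(sim$truth)`), each almost always ordered one
way in controls (`pct_control` near 1 or 0) and the opposite way in
cases, so the 4-pair majority vote classifies the held-out test samples
with 99.6% accuracy and AUC 0.9998. Running
`identifyDiffMirnas(res$stable, res$reversed)` flags exactly the 20
planted miRNAs as differential.

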