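# pcascore

Consensus-NMF molecular subtyping and a PCA-based prognostic risk score for
bulk expression cohorts with survival follow-up.

## What this package is for

Tumor cohorts — the motivating case is low-grade glioma profiled for
RNA-modification "writer" enzymes (m6A/m1A methyltransferases,
alternative-polyadenylation factors, A-to-I editing enzymes) — often split
into molecular subtypes with distinct survival. This package builds a
per-patient prognostic score from such data in the standard staged design:

1. **Subtyping** — consensus non-negative matrix factorization (repeated
   Lee–Seung NMF runs aggregated into a co-clustering matrix), with the
   average silhouette width (ASW) on `1 − consensus` as the consistency
   diagnostic.
2. **Differential expression** — empirical-Bayes moderated t-tests between
   the subtypes, filtered at `|log2FC| ≥ 0.5` and `p < 0.05`.
3. **Characteristic genes** — a binary Harris Hawks optimizer with
   variable-neighbourhood learning (VNLHHO) minimizing the wrapper fitness
   `α·err + (1−α)·|mask|/G` (α = 0.99), where `err` is stratified 5-fold
   cross-validated k-NN error on the masked genes.
4. **Prognostic screen** — univariate Cox *and* median-split log-rank, both
   at `p < 0.001`.
5. **Signature & score** — for the genes passing both 3 and 4, z-score,
   eigen-decompose, and set each patient's score to the sum of the first two
   principal-component projections:
   `score_i = PC1_i + PC2_i`.
6. **Stratification & evaluation** — cutpoint by maximally selected rank
   statistic (minimum 10% per stratum), then Kaplan–Meier curves, log-rank
   test, univariate and covariate-adjusted Cox models, time-dependent AUC at
   1/3/5/7 years (IPCW, cumulative/dynamic), and Harrell's C-index.

The survival machinery (product-limit estimator, log-rank, Cox partial
likelihood with Efron ties, maxstat cutpoint, IPCW AUC, concordance) is
implemented in the package and cross-checked against the `survival` package
in the test suite. A synthetic-cohort generator with planted subtypes,
planted informative genes, and subtype-dependent censored survival makes the
whole chain testable without any data download.

## Worked example

```r
library(pcascore)

cohort <- generate_cohort(cohort_config(seed = 1))   # 500 genes x 120 samples
fit <- pcascore(cohort$expression, cohort$clinical, seed = 1)
summary(fit)
```

```
Consensus-subtype PCA risk score fit
  samples: 120 | genes: 500
  subtypes (k=2, 30 NMF runs): sizes 60/60, ASW = 0.959
  DEGs: 24 | characteristic: 5 | prognostic: 21 | signature: 5
  cutpoint: 0.1851 (high_score_high_risk); strata 68/52
  log-rank chi-square = 58.88 (p = 1.67e-14); C-index = 0.711
  score HR per unit: 1.521 [1.327, 1.744], p = 1.84e-09
  time-dependent AUC: auc_1y = 0.723, auc_3y = 0.797, auc_5y = 0.807, auc_7y = 0.863
  median OS: low = 11.26, high = 1.16 years
  gene subtypes: 22 prognostic genes, ASW = 0.351
```

Reading this: the consensus clustering split the cohort into the two planted
subtypes (ASW 0.96, i.e. near-perfect co-clustering); 24 genes passed the
fold-change/p filter; VNLHHO kept a compact 5-gene characteristic panel
(with α = 0.99 the fitness prefers the smallest panel that still separates
the subtypes — see the methods vignette), all of which passed the prognostic
screen and form the signature. The score's hazard ratio is per score unit;
the high-score stratum has markedly shorter median survival (1.2 vs 11.3
years), and the score discriminates 5-year survival with AUC ≈ 0.81 on this
synthetic cohort. A validation cohort drawn from the same simulated
population can be scored with the frozen model:

```r
valid <- generate_cohort(cohort_config(seed = 99))
pred <- predict(fit, valid$expression, valid$clinical)
pred$evaluation$logrank$p_value
#> [1] 9.783076e-09
```

`plot(fit, "km")`, `plot(fit, "consensus")`, `plot(fit, "fitness")` and
`plot(fit, "score")` show the stratified survival curves, the ordered
consensus matrix, the optimizer trajectory, and the score distribution.
`run_pipeline()` performs the same fit while writing every stage's artifacts
(TSV/JSON) and a digest manifest; `inst/scripts/run-pipeline.R` is a thin
command-line wrapper around it.

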