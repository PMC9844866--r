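---
title: "From molecular subtypes to a prognostic PCA score: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From molecular subtypes to a prognostic PCA score: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcascore)
```

## The analysis in one paragraph

Expression-based prognostic signatures of the RNA-modification "writer" kind
are built in stages: patients are first partitioned into molecular subtypes
from their expression profiles; genes that distinguish the subtypes are
identified; a sparse "characteristic" panel is selected from those genes by a
wrapper optimizer; the panel is intersected with genes that individually
predict overall survival; and the surviving genes are summarized into a
single per-patient risk score — the sum of the first two principal-component
projections of the standardized signature submatrix — which is dichotomized
at a survival-optimal cutpoint and evaluated with standard survival
statistics. `pcascore()` runs the whole chain; each stage is also exported on
its own.

This vignette records the model choices, the tunable parameters, the
numerical conventions, and what the synthetic-cohort tests do and do not
demonstrate.

## Synthetic cohorts: what the generator emulates

Real inputs for this kind of analysis are bulk log2-scale expression matrices
with survival follow-up (for gliomas, typically a training cohort of several
hundred patients and an independent validation cohort). The generator
reproduces the statistical structure the method relies on, not the biology:

* two latent subtypes in proportions `subtype_proportion` (default 1/2);
* `n_informative` genes (default 20 of 500) whose mean is shifted by
  `effect_size * noise_sd` (default 2 standard deviations) in subtype 2 —
  the analogue of a co-regulated writer-gene program;
* all other genes i.i.d. Gaussian around a common baseline (6 on the log2
  scale, `noise_sd` = 1), in both subtypes;
* a latent risk equal to the standardized mean expression of the informative
  genes, entering an exponential survival model with baseline hazard
  `baseline_hazard` (0.2/year) and `log_hazard_ratio` (1) per risk unit;
  censoring is independent exponential (0.1/year, roughly a third of
  samples censored);
* clinical covariates that copy the subtype label and flip with probability
  `covariate_flip_prob` (0.1), so "clinical features differ by subtype"
  holds in kind.

The defaults are the conditions exercised throughout the test suite:
120 samples, 500 genes, 20 informative. Constant hazard was chosen for
closed-form checkability (the Cox model is then exactly specified and the
true hazard ratio known); real cohorts have non-constant hazards, so
calibration results under this generator do not certify proportional-hazards
robustness. The informative genes are placed deterministically (even stride
across the panel) so that cohorts drawn with different seeds are samples
from the *same* population: a signature frozen on one cohort transfers
meaningfully to another, mirroring a train/validate design. Other
deliberately absent features of real data: gene–gene correlation beyond the
planted program, batch structure, heavy-tailed noise, and informative
censoring. Passing tests therefore demonstrate internal correctness and
recovery under the assumed model, not performance on real cohorts.

Expression is emitted on the log2 scale, which is the common unit of public
expression matrices; the non-negativity NMF needs is produced downstream
(below), so the generator does not need to commit to FPKM/TPM conventions.

## Consensus NMF subtyping

Each run factorizes the (shifted) expression matrix as `X ≈ W H` with
Lee–Seung multiplicative updates for the squared Frobenius objective, which
is non-increasing under the updates — the property the tests assert at every
iteration. Input with negative entries is shifted by its global minimum;
this is the least intrusive way to reach the NMF domain and preserves every
between-sample contrast. Samples are assigned to the dominant factor of `H`.
Because the factorization is invariant to a diagonal rescaling of `W` and
`H`, "dominant" is only defined after fixing a convention: we L2-normalize
the columns of `W` and move the scale into `H` before taking the arg-max
(ties toward the lower factor index).

Thirty random restarts (`n_runs`) are aggregated into a consensus matrix of
co-clustering frequencies; average-linkage hierarchical clustering of
`1 − consensus` cut at `k` gives the final labels, relabelled
deterministically in order of first appearance. Cluster-number choice is
left to the user (`k = 2` is the default two-subtype design). Consistency is
reported as the average silhouette width on `1 − consensus` — the
"clustering consistency" reading of that diagnostic — plus the cophenetic
correlation. Restart-based consensus (rather than subsample-based) was
chosen because the planted-structure recovery it is tested against uses the
full cohort in every run; both variants coincide in the noiseless limit.

## Differential expression and the DEG filter

Subtype markers come from gene-wise pooled-variance t-tests with
empirical-Bayes variance moderation: gene variances are shrunk toward a
scaled inverse-chi-square prior fitted by moment matching on the log
variances, and the prior degrees of freedom are added to the residual
degrees of freedom. `prior_df = 0` recovers the ordinary pooled t-test
exactly (a test asserts equality to 1e-10), and the moderated fit tracks the
`limma` empirical-Bayes implementation closely on the same data — `limma`
serves as an independent cross-check, never as the implementation. Note that
the generator's homoskedastic genes drive the estimated prior degrees of
freedom to infinity (complete shrinkage); heteroskedastic data give the
familiar finite prior.

The marker filter keeps genes with `|log2FC| >= 0.5` (inclusive) and raw
`p < 0.05` (strict), the usual reporting convention for this filter; the
Benjamini–Hochberg FDR is reported alongside for transparency but is not
used to filter.

## VNLHHO: the characteristic-gene selector

The wrapper fitness of a gene mask is
`alpha * err + (1 - alpha) * |mask| / G` with `alpha = 0.99`, where `err` is
the stratified 5-fold cross-validated error of a 5-nearest-neighbour
classifier on the z-scored masked submatrix. Folds are drawn once per run,
so fitness is a deterministic function of the mask and the best-so-far
trajectory is provably monotone. The empty mask scores `+Inf`.

Candidate masks are explored by a binary Harris Hawks optimizer: hawks carry
continuous positions in `[0,1]^G`, binarized through the sigmoid transfer
`S(v) = 1/(1 + exp(-10(v - 0.5)))` with fresh uniform thresholds; the
escaping energy `E = 2 E0 (1 - t/T)` switches exploration (perching on
random hawks, moves relative to the population mean) to exploitation (soft
and hard besieges, progressive rapid dives with Mantegna Lévy flights,
exponent 1.5). A variable-neighbourhood learning step follows each HHO
sweep: hawks sit on a ring and move a random half of their coordinates
toward the best solution within ±k ring positions, with k growing from 1
(up to 3) after 5 stagnant iterations and resetting on improvement.
Defaults: 30 hawks, 100 iterations.

Two concretizations matter and were fixed after measuring their effect on
planted-recovery behaviour (both are deliberate design choices of this
package):

* **The prey is the rabbit's realized subset.** Besiege and dive moves
  target the best-known *binary* solution rather than its continuous
  position. Corners are absorbing under the transfer function, so the late
  phase becomes a stochastic local search in subset space; besieging an
  interior position leaves selection probabilities mid-range and the search
  cannot accumulate gene-identity information.
* **Moves are kept only when not worse.** Unconditional acceptance collapses
  the population onto the rabbit and costs most of the evaluation budget in
  duplicates; strict-improvement acceptance preserves diversity; accepting
  ties additionally lets hawks drift across equal-fitness plateaus. Dives
  remain strictly improve-only, and the rabbit update is strictly greedy,
  so the best-so-far invariant is untouched.

Two properties of this design are worth stating plainly. First, with
`alpha = 0.99` the sparsity term dominates whenever the cross-validated
error ties at zero, so on strongly separated cohorts the optimizer converges
to a *minimal* separating subset — typically 5–10 genes rather than the full
planted program. That is the fitness's optimum, not a search failure; users
who want fuller recovery of a co-regulated program should lower `alpha` or
use the DE filter output directly. Second, the evaluation budget is
`O(pop_size * max_iter)` while the subset space is `2^G`; exhaustive-optimum
matching on tiny panels degrades as G grows toward the budget (measured:
20/20 matches at G = 8, 18/20 at G = 10, 14/20 at G = 12 over 20 seeds at
the defaults).

## Survival machinery

All survival statistics are implemented from first principles in this
package — they are part of what is being built and tested, with the
`survival` package used as an independent oracle in the test suite:

* **Product-limit curves** with the censored-after-event convention; the
  median is the first time the curve reaches 0.5. Without censoring the
  curve equals `1 − ECDF` exactly.
* **Two-group log-rank test** from the hypergeometric moments at each
  distinct event time; the signed standardized statistic is exposed because
  the cutpoint search maximizes its absolute value.
* **Cox proportional hazards** by Newton–Raphson on the partial likelihood
  with Efron tie handling (the modern default; the choice only matters with
  ties), step-halving, Wald intervals from the observed information, and a
  non-convergence / monotone-likelihood flag. Coefficients, standard errors
  and log-likelihoods agree with `coxph` to 1e-6 on tied data.
* **Prognostic screen**: a gene passes at level `alpha` only if the
  univariate Cox fit on its standardized expression *and* the log-rank test
  on its median split both reject — the stricter reading of a combined
  Kaplan–Meier/Cox screen, configurable to either-test. The median split is
  used because no other split is canonical for a screening step.
* **Maximally selected rank statistic**: the cutpoint maximizing the
  absolute standardized log-rank statistic over all splits between
  consecutive distinct score values leaving at least `minprop = 0.1` of
  samples per side; ties break toward the lower cutpoint, and a sample
  exactly at the cutpoint is "low". The selection-adjusted p-value is
  available by permutation (`n_perm`, off by default — the pipeline uses the
  cutpoint, not its p-value).
* **Time-dependent AUC**: cumulative-case/dynamic-control with inverse
  probability-of-censoring weights from the product-limit estimate of the
  censoring distribution (cases weighted at the left limit of their event
  time, controls at the horizon). Without censoring it reduces exactly to
  the Mann–Whitney statistic.
* **Harrell's C** over usable pairs, score ties counting one half.

## The PCA score

Signature genes are z-scored with *training* means and standard deviations;
the sample covariance of the standardized genes is eigen-decomposed and the
first two components retained. The per-sample score is the sum of the PC1
and PC2 projections. Summing two projections (rather than, say, weighting by
explained variance) follows the GGI-style score construction this family of
signatures uses; the alternative reading — a loading-weighted sum over genes
— is algebraically a different linear functional and is intentionally not
implemented. PCA's sign indeterminacy is resolved by orienting each loading
vector so its largest-absolute entry is positive, making fits bit-for-bit
reproducible; which direction of the score is "bad" is then *learned* from
the training survival data (stored as `risk_direction`) rather than assumed.
Validation cohorts are scored with the frozen model — refitting means or
loadings on validation data would leak information.

Degenerate cases: a zero-variance signature gene is an error (it carries no
direction); a second eigenvalue at numerical zero flags `degenerate_pc2`
and the score gracefully reduces to PC1.

## Pipeline seeds, determinism, and problem sizes

A single master seed derives fixed per-stage seeds (offsets 101, 202, 303),
so changing one stage's settings never perturbs another stage's stream, and
two runs of `run_pipeline()` with the same configuration are byte-identical
(the manifest records md5 digests and no timestamps; cohort text files print
doubles with `%.17g`, which round-trips IEEE doubles exactly). The signature
is always a subset of the DEG list, of the selector output, and of the
prognostic list, and an empty signature aborts with a stage-named error
rather than a silent success.

The test suite and the acceptance script run at the generator's default
problem sizes (120 samples, 500 genes, 30 consensus restarts, 30 hawks, 100
iterations) with a few smaller instances for exhaustive oracles; a full
suite completes in roughly ten minutes on one core.

## Known limitations

* Consensus NMF is restart-based; subsampling-based consensus would add a
  stability dimension the current diagnostic does not measure.
* The selector's minimal-subset bias under `alpha = 0.99` (above) means
  "characteristic genes" is a compact discriminative panel, not the complete
  differential program.
* The prognostic screen tests each gene marginally; correlated prognostic
  genes can pass or fail together.
* The permutation p-value for the cutpoint is exchangeable-null; it does not
  condition on the censoring pattern.
* No covariate adjustment in the differential-expression model; the
  multivariate Cox adjustment happens only at evaluation time.
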