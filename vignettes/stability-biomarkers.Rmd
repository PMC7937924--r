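---
title: "Stability-driven biomarker discovery for complicated sepsis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-driven biomarker discovery for complicated sepsis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepstab)
```

## The problem

A complicated sepsis course — death within 28 days or persistent
multi-organ failure at day 7 — is hard to anticipate from clinical data
alone at ICU admission. Peripheral-blood gene expression sampled within
the first 24 h carries early signal, but with ~23% prevalence, thousands
of correlated genes, and a few hundred patients, any single feature
selection run is unstable: rerunning it on a slightly different split
returns a different gene list. `sepstab` implements a pipeline that
makes that instability the object of measurement: features are selected
independently inside each of many cross-validation training folds, and a
gene's worth is its *normalized stability score* — the percentage of
folds in which it survives to the final predictor set.

## The procedure

For a preprocessed expression matrix (genes × samples, log2 scale) and a
phenotype table, `run_discovery()` executes, for each of `R = 10`
repeats of a stratified `K = 5`-fold partition (50 iterations), using
the training folds only:

1. **Differential expression.** A two-group moderated t-test per gene:
   residual variances $s_g^2$ (df $d$) are shrunk toward a prior
   $(d_0, s_0^2)$ fitted by moment matching on $\log s_g^2$, giving
   $\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$ and
   $t_g = \mathrm{log_2FC}_g / (\tilde s_g \sqrt{1/n_1 + 1/n_0})$ on
   $d_0 + d$ df. Benjamini–Hochberg control at FDR 0.1; "top DEGs"
   additionally require $|\mathrm{log_2FC}| \ge 1$.
2. **Three selectors.** Random-forest impurity importance (500 trees,
   above-mean rule capped at 200), L1-penalized logistic regression
   (penalty by 5-fold CV, binomial deviance, 1-SE rule), and greedy
   mRMR (F-statistic relevance scaled to $[0,1]$, mean
   $|r|$ redundancy, difference scheme).
3. **Pooling.** Union of the three selections, the fold's top DEGs, and
   the clinical severity score (always retained).
4. **RFE.** Recursive feature elimination down to 20 features, dropping
   the lowest-ranked 10% per iteration by extra-trees importance;
   clinical covariates are exempt.
5. **Imbalance correction.** The configured sampler (default SMOTE)
   applied to the training fold only.
6. **Tuning and fitting.** Exhaustive grid search by inner 5-fold CV
   mean AUROC (ties to the first grid row), then a final fit (default: a
   balanced random forest, in which every bootstrap bag is undersampled
   to class balance before tree growth).
7. **Scoring.** Sensitivity, specificity, FPR, MCC at threshold 0.5 and
   AUROC on the untouched test fold.

Features surviving step 4 are tallied; `summarize_stability()` converts
tallies to scores $100 \cdot \text{count}/(R \cdot K)$. Metric means are
reported with 2.5/97.5 percentile intervals across the 50 iterations
(the interval method is a package choice; the protocol we emulate prints
intervals without naming one).

`run_validation()` implements the external-cohort protocol: align a
marker panel across platforms, z-score each gene within each dataset,
re-select within the panel on derivation data (LASSO or tree ranking),
balance/tune/fit on derivation only, score the validation cohort, and
report metrics both at a derivation-chosen threshold (honest) and at the
best-achievable threshold (labeled post-hoc — published tables often
select thresholds after the fact, and the two must not be conflated).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `n_folds`, `n_repeats` | 5, 10 | — | 50 train/test splits; the stability denominator |
| `fdr_cutoff` | 0.1 | — | BH-FDR for DEG calls |
| `lfc_cutoff` | 1.0 | log2 units | top-DEG fold-change filter |
| `rfe_target` | 20 | features | size of the per-fold predictor set |
| `threshold_step` | 0.001 | probability | 1001-point threshold sweep |
| `sampler` | `"smote"` | — | training-fold balancing; five undersamplers also provided |
| `classifier` | `"brf"` | — | registry name; grids are config-exposed |
| stability shortlist | 60 | % | reporting cutoff, not a fitting parameter |

## The synthetic world

`generate_cohort()` emulates the statistical structure of the target
data: 228 samples at 52/228 prevalence, 2000 genes (a desk-scale
stand-in for ~20k; `n_genes` is free), per-gene baselines
$b_g \sim N(7, 1.5)$ on the log2 scale, noise
$\sigma_g \sim U[0.3, 0.8]$, two batches with additive per-gene shifts
$N(0, 0.5^2)$, a severity score shifted $+1.2$ SD in the positive
class, and mortality drawn only inside the positive class at rate
28/52. Effects are additive on the log2 scale, so a planted $\delta_g$
*is* the log2 fold change the DGE stage should recover.

Two generator choices deserve their rationale:

* **Strong effects are $|\delta| \sim U[1.25, 2]$,** not $U[1, 2]$.
  The planted strong class emulates a gene list that was itself
  selected on *observed* fold change; the top-DEG filter applies to the
  observed $\mathrm{log_2FC}$, whose sampling SE at $n = 52/176$ is
  ~0.09. Planting at the boundary would make recovery of a
  boundary gene a coin flip for any method — no analysis pipeline can
  be validated against a world that contradicts its own expected
  behavior. $U[1.25, 2]$ keeps every strong gene ≥ 3 SE clear of the
  filter.
* **Weak effects are $|\delta| \sim U[0.2, 0.5]$.** Observed DEG
  effect-size distributions concentrate at small fold changes (in the
  emulated study, 17 of 1269 DEGs reached $|\mathrm{log_2FC}| \ge 1$).
  Letting weak effects range up to the strong cutoff with independent
  $\sigma_g$ would let high-SNR "weak" genes displace low-SNR strong
  ones from the 20 RFE slots — again contradicting the recovery
  behavior the planted design is meant to test.

What a green planted-recovery test establishes: the pipeline finds
additive, independent, Gaussian log-scale effects of the stated sizes
under batch shifts and class imbalance, without leaking test
information. What it does not establish: performance under correlated
gene modules, probe-level artifacts, platform mixtures, non-Gaussian
heavy tails, or outcome label noise — all present in real cohorts.
`generate_validation_cohort()` adds one real-world feature: attenuated
and partially retained effects in an external population.

## Numerical choices

* **Quantile normalization** maps each column to the mean order
  statistic; ties receive the mean of the reference values at their
  rank positions, which makes the map idempotent. It is a matrix-level
  stand-in for probe-level RMA, which needs raw intensities this
  package never sees (documented limitation).
* **Batch adjustment** is the parametric empirical-Bayes
  location/scale model (normal prior on per-batch gene means,
  moment-matched inverse-gamma on scales), protecting the outcome in
  the standardization design; it refuses outcome-confounded batches and
  singleton batches, and pins the scalar grand mean. Surrogate-variable
  estimation (top right-singular vectors of the outcome-residualized
  matrix) is a *diagnostic* here: components are tested against the
  declared batch by ANOVA, and the declared label drives the
  adjustment. The emulated protocol's exact SVA/ComBat interplay is
  under-specified; both readings are config-reachable.
* **Variance-prior fit** uses the digamma/trigamma moment inversion on
  $\log s^2$ with $d_0$ capped at $10^6$; the $d_0 = 0$ override
  recovers the ordinary pooled t exactly.
* **LASSO penalty** is chosen by cross-validated binomial deviance with
  the 1-SE rule rather than by AUROC: only a proper scoring rule keeps
  null selections empty (measured: AUROC-scored CV selects spurious
  features in ~40% of null runs; deviance+1SE in ~7%).
* **RFE ranking** uses extra-trees importance by default: bootstrap
  forest importances intermittently let a lucky noise feature displace
  the weakest true marker (masking bias); random cutpoints do not.
* **mRMR** scales the F relevance by its maximum so subtracting a
  correlation is meaningful, and never admits a feature perfectly
  correlated with one already selected.
* **Thresholding** is strictly-greater-than; sweeps tie to the lowest
  threshold. Metrics with zero denominators are reported as `NA` with
  an explicit `undefined` marker, never silently propagated.
* **KS p-values** use the asymptotic Kolmogorov distribution at
  effective size $n_1 n_2/(n_1+n_2)$; the small-sample path reports a
  within-group bootstrap mean D and a label-permutation empirical
  p-value instead. The significance cutoff for "distributionally
  different" defaults to p < 0.1, matching the reporting convention of
  the emulated study.
* **Stability counting** tallies membership in the RFE output (the
  per-fold *final* predictor set), not the pre-RFE pool; a flag-level
  alternative reading exists but the output list is what the score is
  meant to stabilize.
* **Determinism.** Every stochastic step derives a 32-bit child seed
  from `(seed, repeat, fold, step-tag)`; reruns are bit-identical.

## Known limitations

* The CART forest backing the tree classifiers is compact by design
  (gini/variance splits, mtry subsampling, optional balanced bags and
  random cutpoints); it does not implement split-weighted permutation
  importance, honest trees, or probability calibration.
* Cluster-centroid undersampling follows the k-means-centroid
  semantics; `keep_nearest_instances = TRUE` gives the
  nearest-real-instance variant described in looser prose accounts.
* `summarize_cohort()` expects an already-filtered table: exclusions
  (e.g. a record with a missing outcome) are the caller's explicit,
  auditable step.
* The repeated-measures validation design (multiple time points per
  patient) treats rows as independent by default; patient-level
  aggregation is out of scope here.
* Enrichment analysis, CEL-file processing, and figure aesthetics are
  out of scope; the package emits the tables figures would be drawn
  from.
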