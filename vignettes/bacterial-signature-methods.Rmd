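---
title: "Deriving a sparse blood gene signature that rules out bacterial respiratory infection"
author: "bactsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving a sparse blood gene signature that rules out bacterial respiratory infection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bactsig)
```

## The problem

Adults hospitalized with acute respiratory infection (ARI) are very often
given antibiotics "just to be safe", although most ARI is viral. The host
transcriptional response in whole blood differs between bacterial and
viral infection, so a small panel of blood mRNAs can, in principle,
support a decision to *withhold* antibiotics. The clinically useful
contrast is **any bacterial involvement** (bacterial alone, `B`, plus
mixed viral–bacterial, `VB`) versus **nonbacterial** ARI (viral alone,
`V`): antecedent viral infection is common in bacterial pneumonia, and a
classifier that keys only on interferon-driven "viral" genes would
misclassify mixed infections. A rule-out test must prioritize
sensitivity; its clinical value is summarized by the negative predictive
value (NPV) over the range of bacterial prevalences a clinician might
face.

`bactsig` implements the complete analysis as a reusable, tested
pipeline: count-level quality control, differential expression,
derivation of a parsimonious penalized-regression signature with
batch-aware nested cross-validation, and a sensitivity-anchored
classification threshold with NPV reporting — together with a
negative-binomial cohort simulator so that every stage can be validated
against a known ground truth.

## The synthetic cohort generator

Real cohorts of this kind are rarely depositable, so the package treats
the simulator (`sim_config()`, `simulate_cohort()`) as a first-class,
tested module. Counts for gene $g$ in sample $s$ are drawn

$$K_{gs} \sim \mathrm{NB}\!\left(\mu_{gs},\, \alpha_g\right),\qquad
\log_2 \mu_{gs} = b_g + e_{g,c(s)} + u_{g,\beta(s)} + \log_2\!\frac{L_s}{10^6},$$

with baseline log2-CPM $b_g$, class effect $e$, a per-gene batch shift
$u$ and library size $L_s$; the NB variance is
$\mu + \alpha\mu^2$.

Default choices, and why:

* **Classes and batches.** 280 V / 129 B / 95 VB cases plus 64
  non-infected controls across 7 sequencing batches, the composition of
  the cohort the pipeline is designed for. Samples of every class are
  dealt round-robin over batches, so batch never confounds class — which
  matches the design assumption that batch is a technical unit usable
  for cross-validation.
* **Genes.** 8,400 genes with baseline log2-CPM drawn from
  $\mathcal N(3.5, 2.2^2)$, so that roughly 7,000–8,000 survive the
  mean-CPM ≥ 2 expression filter, as in a typical globin-depleted
  whole-blood library.
* **Planted signature.** Four genes: three elevated 1.5 log2-fold under
  any bacterial infection and one interferon-like gene elevated 2
  log2-fold under viral infection. Mixed `VB` samples carry the
  bacterial effects in full and the viral effect attenuated by 0.5
  (configurable), reflecting that bacterial markers do not distinguish
  `B` from `VB` while interferon markers show intermediate levels in
  mixed infection. Signature baselines are drawn from a well-expressed
  stratum so the planted signal cannot be removed by the expression
  filter.
* **Dispersion.** $\alpha_g$ is log-normal around the trend
  $0.35 + 3/\bar{\mathrm{cpm}}_g$ (scatter `sdlog` 0.4), i.e. substantial
  inter-patient biological variability at high expression plus extra
  shot noise for weakly expressed genes — heterogeneous hospitalized
  adults are far from replicate cell lines. Under these defaults a
  single planted gene separates the classes with AUC ≈ 0.85, and the
  Bayes-optimal score over the four genes (stored per sample in the
  simulation truth, with its Monte-Carlo theoretical AUC) reaches
  AUC ≈ 0.95–0.99 depending on configuration.
* **Weak background DE.** By default 40% of genes carry small
  bacterial-direction effects (log-normal magnitude around 0.35 log2,
  random sign), so differential-expression stages see a realistic mix of
  strong, marginal and null genes.
* **Batch shifts** are mean shifts of SD 0.3 log2 applied to every gene,
  with no batch-by-class interaction — the simplest structure consistent
  with using batch as a cross-validation unit. The magnitude is a
  placeholder to be sensitivity-tested, not an estimate of any
  particular study.
* **Library sizes** are log-uniform on 8–30 million, emulating unequal
  sequencing depth.

`simulate_validation_cohort()` redraws everything an independent study
would change — baselines, batches, library sizes, an optional global
rescaling — while preserving the signature genes and directions,
emulating external validation on independently processed data.

What the simulator does *not* emulate: read-level artifacts, gene length
and GC effects, correlated co-expression modules, batch-by-class
confounding, or label noise from imperfect clinical adjudication.
Passing the recovery and calibration suites therefore demonstrates that
the estimator is correct and honest under its own model assumptions, not
that any particular clinical performance will be attained on real data.

## Quality control

The filter cascade (`preprocess_counts()`) is: mean-CPM gene filter →
PCA sample-outlier removal → CPM recomputation → batch-variance gene
filter. Where the underlying procedure is standard but its parameters
are genuinely open choices, the package fixes explicit defaults:

* **Expression filter**: a gene is removed iff mean CPM < 2; equality is
  retained, matching the strict inequality of the rule.
* **PCA outliers**: on gene-centered log2(CPM+1), a sample is flagged
  iff any of its first 2 principal-component scores lies more than 6
  robust SDs (median ± MAD-scaled) from the component median. The rule
  is deterministic; both the number of components and the multiplier are
  configurable because different cohorts may need different
  stringency. At these defaults, planted compositional outliers are
  recovered essentially perfectly while homogeneous cohorts lose no
  samples.
* **CPM is recomputed after sample removal**, since removing samples
  changes nothing per-sample but downstream statistics should not depend
  on samples that were judged artifactual.
* **Batch-variance filter**: per gene, a one-way between/within-batch
  sum-of-squares decomposition on log2 CPM; genes with between-batch
  fraction > 0.5 are removed. Batches with fewer than two samples are
  excluded from the estimate with a warning. This filters genes whose
  measurement is dominated by run effects instead of adjusting
  expression values — the pipeline deliberately never "corrects" batch,
  it filters genes and uses batch as a cross-validation unit.

The pseudocount in $\log_2(\mathrm{CPM}+1)$ is 1, for zero-safety and
scale stability at low expression.

## Differential expression

The DE stage is a deliberately simplified two-group negative-binomial
Wald test: median-of-ratios size factors (geometric mean rescaled to 1;
total-count fallback with a warning when no gene is expressed
everywhere), method-of-moments dispersions pooled within class and
shrunk on the log scale (weight 0.5) toward a fitted $a_0 + a_1/\mu$
trend with non-negativity enforced, delta-method standard errors of the
log2 fold change (with a half-count pseudocount guard), two-sided normal
p-values and Benjamini–Hochberg adjustment implemented from the step-up
definition. Genes with zero counts in both groups are flagged with
$p = 1$.

This replaces the full GLM machinery of dedicated DE packages
(Cox–Reid dispersions, shrunken fold changes, independent filtering,
outlier handling) because the pipeline needs a calibrated DE *ranking*
as a stage, not package parity; under label permutation its type-I error
at $p<0.05$ is nominal (checked to 0.05 ± 0.01 in the acceptance suite).
The test models group only; whether a batch covariate belongs in the DE
model is left open, and the batch question is addressed instead by the
leave-one-batch-out (LOBO) consistency analysis
(`lobo_de_consistency()`): the fraction of full-data significant genes
that remain significant when each batch is left out in turn. On
batch-free strong-signal cohorts this fraction exceeds 0.9; planting
batch-driven signal in a subset of genes makes it drop, which is exactly
the failure mode the analysis exists to expose.

## The signature estimator

The core estimator (`fit_signature()`) is a *hard-thresholded, mostly
relaxed, LASSO-constrained logistic regression*:

1. **Transform.** Features are per-gene standardized $\log_2(CPM+1)$
   values; the centering/scaling constants are part of the model and are
   always fit on training data only (per outer fold during
   cross-validation).
2. **Penalized path.** For a decreasing penalty sequence $\lambda$, the
   coordinate-descent solver (Rcpp, IRLS with strong-rule screening,
   warm starts and a full KKT check at every solution; solutions satisfy
   the KKT conditions to $10^{-7}$) minimizes mean logistic deviance
   plus $\lambda\|\beta\|_1$ with an unpenalized intercept. The default
   path has 15 log-spaced values down to $0.1\,\lambda_{\max}$.
3. **Relaxation.** For relaxation weight $\gamma$, coefficients are the
   standard relaxed-lasso blend
   $\beta(\gamma) = \gamma\,\beta_{\text{lasso}} +
   (1-\gamma)\,\beta_{\text{refit}}$, where the refit is the unpenalized
   logistic fit on the active set (ridge-stabilized with penalty
   $10^{-6}$ if separable). The default grid
   $\gamma \in \{0, 0.1, 0.25, 0.5, 1\}$ is concentrated near 0 —
   "mostly relaxed" — with ties broken toward small $\gamma$.
4. **Hard threshold.** Coefficients with $|\beta_j(\gamma)| < \tau$
   (standardized scale) are zeroed and the survivors refit at the same
   $\gamma$; $\tau = 0$ is the identity. Thresholding fitted
   standardized coefficients (rather than univariate statistics) is the
   default interpretation; default grid $\tau \in \{0, 0.05, 0.1,
   0.25\}$.
5. **Batch-aware tuning.** `tune_signature_lobo()` scores every grid
   point by pooled held-out AUC over leave-one-batch-out folds, subject
   to a **sparsity budget**: the median active-set size across folds
   must not exceed 6 genes (configurable, disable with `Inf`). The
   budget makes the parsimony goal explicit rather than hoping it
   emerges; the final fitted model is also capped at the budget by a
   rank-based hard threshold with refit. Ties are broken toward sparser
   models, then larger $\lambda$, then smaller $\gamma$, then larger
   $\tau$.
6. **Nested evaluation.** `cv_signature()` wraps the *entire* procedure
   in an outer LOBO loop: for each held-out batch, tuning happens in an
   inner LOBO over the remaining batches only, and the tuned model
   (with its own transform) scores the held-out batch. The pooled
   held-out AUC is the headline CV-AUC; per-fold AUCs are reported
   alongside, since pooling versus averaging is a genuine convention
   choice. No held-out sample ever influences its own scorer, which the
   test suite verifies by refitting fold scorers from scratch.

Two computational guards shape the searched grid without affecting the
selected models in practice: relaxed ($\gamma<1$) refits are evaluated
only for active sets of at most `refit_cap = 25` genes, and the penalty
path exits early (glmnet's `dfmax` convention) once the active set
exceeds that cap. Under a budget of 6 genes, denser solutions can win
the tuning only through the pure-lasso column, which needs no refit;
without the cap, label-permuted (null) data — where the path quickly
absorbs over a hundred spurious features whose unpenalized refits are
all separable — costs two orders of magnitude more compute for grid
points that are never selectable.

Features are all filtered genes; no DE pre-selection is applied by
default, keeping differential expression and signature derivation as
separate analyses (a DE pre-filter can be emulated by subsetting the
matrix). The inner selection metric is AUC rather than deviance because
discrimination is the quantity the signature exists for.

All fitting is deterministic given the data and grid; the only
randomness anywhere is in cohort simulation, governed by a single
integer seed.

## Threshold, NPV and external validation

`threshold_for_sensitivity()` anchors the classifier at a sensitivity
floor (default 90%): under the rule "score ≥ t ⇒ bacterial", it returns
the largest threshold whose sensitivity meets the floor — equivalently,
the specificity-maximizing threshold subject to it (verified against
exhaustive cut-point search). The report carries the confusion counts
and

$$\mathrm{NPV}(\pi) = \frac{Sp\,(1-\pi)}{Sp\,(1-\pi) + (1-Se)\,\pi},
\qquad
\mathrm{PPV}(\pi) = \frac{Se\,\pi}{Se\,\pi + (1-Sp)(1-\pi)}$$

over a prevalence grid (default 5%–50% in steps of 5, covering the
plausible planning range for bacterial ARI). At the operating point
$Se = 0.90$, $Sp = 0.71$ these identities give NPV ≈ 91% at 40%
prevalence and > 95% below 25% — the arithmetic any user of the
signature should be able to reproduce. Non-infected controls are never
part of supervised fitting; they are scored and classified at the
derived threshold, and the fraction called nonbacterial is reported.

`evaluate_external()` scores an independently processed cohort in two
transform modes — training constants carried over (exactly how fixed
coefficients would be deployed) and constants refit on the external
cohort (absorbing global processing shifts) — because independently
processed data leave the rescaling convention genuinely ambiguous. Both
AUCs are reported to expose the gap; CPM itself already absorbs pure
library-size rescaling exactly.

## Numerical choices

* Coordinate-descent tolerance $10^{-10}$ (weighted-scale coefficient
  change), IRLS exit at $10^{-9}$ linear-predictor change, KKT
  feasibility $10^{-8}$; objectives match an independent convex solver
  to well under $10^{-5}$ on random instances.
* Logistic weights floored at $10^{-6}$; glm refits capped at 15 IRLS
  iterations before the ridge-stabilized ($10^{-6}$) Newton fallback
  (20 iterations, objective-based early exit).
* AUC uses average ranks, i.e. ties count one half; the ROC curve
  enumerates every distinct score.
* Dispersion estimates are floored at $10^{-8}$; constant and all-zero
  genes follow explicit degenerate contracts rather than producing NaN.
* Gene-wise transforms floor the scale at $10^{-8}$, mapping constant
  genes to zero rather than dropping them at scoring time.

## Problem sizes used by the checks

The automated checks run on scaled-down cohorts chosen to keep the full
suite fast while preserving the study's structure: recovery and
calibration use 50 replicates of 7-batch cohorts with 2,000 genes and
250 samples (139 V / 64 B / 47 VB), the null-calibration cohorts use 800
genes and 210 samples, and the LOBO-consistency analogue uses 2,000
genes with 400 strongly differentially expressed background genes. The
acceptance script re-runs the same computations at a dozen replicates on
the same cohort shapes.

## Limitations

* The DE stage is a simplified NB Wald test; it is calibrated under the
  null but does not reproduce any specific package's fold-change
  shrinkage or outlier handling.
* Signature genes, coefficients and score thresholds are properties of
  the cohort they were derived on; this package provides the
  *procedure* and its analytic identities, and absolute thresholds do
  not transfer across cohorts without recalibration.
* Batch effects are modeled (and filtered) as mean shifts only; a cohort
  with batch-by-class confounding violates the design assumptions of
  both the simulator and the cross-validation unit.
* With fewer than 3 batches the nested procedure is undefined; with 3,
  the inner tuning degenerates to 2-fold LOBO.
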