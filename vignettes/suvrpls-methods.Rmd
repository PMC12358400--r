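---
title: "Methods: voxel-wise SUVR statistics and PLS classification"
author: "suvrPLS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-wise SUVR statistics and PLS classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`suvrPLS` analyzes cohorts of volumetric PET tracer-uptake images, one
per subject in a common space, together with a subject table (diagnosis,
age, sex, site, illness duration, symptom scores). The scientific
question it serves is whether the whole-brain *pattern* of
AMPA-receptor-tracer SUVR separates bipolar from unipolar depression
when univariate regional differences overlap too much to classify
individuals. Its pipeline has five stages — SUVR preparation, voxel-wise
group statistics with cluster-level FDR, multi-response PLS
classification, leave-one-pair-out cross-validation with per-subject
averaging, and ROC/Youden evaluation — plus a synthetic-cohort generator
that provides ground truth for all of them.

## SUVR preparation

A SUVR volume is the uptake volume divided by its mean over the brain
mask, so the in-brain mean is exactly 1 and the operation is
idempotent. Smoothing is separable Gaussian convolution parameterized by
FWHM (mm), with `sigma = FWHM / (2 * sqrt(2 * log(2)))` converted to
voxel units per axis. The boundary rule is half-sample symmetric
reflection: it preserves constants exactly, conserves the total
in-volume sum for symmetric kernels, and is deterministic. Site
harmonization applies a site-specific filter (e.g. 5 mm FWHM for a
higher-resolution scanner) before the common 8 mm smoothing; composing
the two Gaussians is equivalent to one kernel with
`sigma^2 = sigma_5^2 + sigma_8^2`, which the tests verify on impulse
inputs.

The analysis mask for classification keeps voxels whose SUVR exceeds
0.9 in **every** subject — a conjunction, so one low-signal subject
removes a voxel. The mask is computed on the smoothed SUVR volumes of
all subjects (training and test alike). The text this design follows
describes the mask as computed "across all participants" without a
per-fold restriction, and we take that reading as the default;
`runCV()` accepts arbitrary predictor matrices, so a strict
train-only-mask variant can be composed by the user per fold, but it is
not the default behavior. Voxel statistics run on a broader mask — the
generator's brain mask stands in for a ">10% gray-matter probability"
map; with real tissue-probability volumes, `probabilityMask()` applies
any threshold.

## Voxel-wise statistics and cluster-level FDR

Group comparison is the pooled-variance two-sample Student t per voxel
(BD − MDD; `df = n1 + n2 - 2`, constant across voxels). Zero-variance
voxels get `t = 0` when the group means agree and are excluded with a
warning otherwise. One-tailed analyses run separately per direction with
forming threshold `qt(1 - alpha, df)` (1.68 at df = 41, alpha = 0.05).

Cluster-level FDR is realized by permutation calibration rather than
random-field theory: suprathreshold voxels are labeled into 26-connected
components; each observed cluster's p-value is the tail probability of
the **maximum cluster size** under diagnosis-label shuffling (with the
`(1 + #{exceedances}) / (B + 1)` correction, so p is never zero); and
Benjamini–Hochberg runs across the observed clusters at level `q`.
Random-field smoothness estimation is out of scope for this package and
the permutation route is exactly testable against ground truth.

Two numerical properties of this design are worth knowing:

* **Granularity.** With `B` permutations the smallest attainable
  p-value is `1/(B + 1)`; BH with `m` observed clusters requires the
  top-ranked cluster to reach `q/m`. At the default forming threshold
  (alpha = 0.05) the noise typically contributes 10–40 small clusters,
  so `B` must be at least a few hundred per `q/m` unit for rejections to
  be possible at all. The pipeline default is `B = 1000`.
* **Contamination under strong sharp effects.** Label permutations do
  not remove the seeded effect from the data; a permuted split with an
  imbalanced allocation of true-BD subjects recreates a fraction of the
  effect at the same location. For a spatially *sharp* effect whose
  voxel-level t is far above the forming threshold, those partial
  effects also exceed the threshold across the whole region, so the
  maximum-size null becomes heavy at exactly the observed cluster size
  and power drops. The statistic is most sensitive when the effect's
  voxel-level t sits a safe margin above the threshold (around 4–5)
  while partial fractions of it stay below. This is why, on synthetic
  cohorts with the default ±0.1 SUVR effects and default noise, the
  pipeline frequently reports a large low-p cluster that does not
  survive BH at `q = 0.05`; the ground-truth recovery test uses an
  effect in the sensitive regime (voxel t near 5, 43 subjects).

## Multi-response PLS (PLS2)

X (subjects × masked voxels) and Y (subjects × responses) are column
centered; X is **not** scaled to unit variance by default because SUVR
voxels share one physical scale (a `scale` flag exists). The response
block is `disease` (0 = MDD, 1 = BD) plus the nuisance covariates age,
sex (0/1) and site as one-hot columns with all levels retained
(centering absorbs the redundancy), optionally plus illness duration.
Fitting the block jointly lets the latent components account for
confound structure while only the `disease` column of the prediction is
used for classification.

Per component `a`, NIPALS PLS2 seeks the fixed point
`w ∝ X_a' u`, `t = X_a w`, `q ∝ Y_a' t`, `u = Y_a q`. Instead of
running the power iteration, the package computes that fixed point
exactly: `q` is the dominant eigenvector of the responses × responses
matrix `Z'Z` with `Z = X_a' Y_a`, making `w ∝ Z q` the leading left
singular vector of `Z`. The fit is therefore deterministic with no
convergence tolerance; the sign is anchored so that `q` is positive on
the highest-variance response column (ties broken by the lowest column
index). X-deflation (`X_{a+1} = X_a − t p'`) is carried lazily through
the stored scores and loadings rather than by rewriting the wide
matrix. Components stop early, with a warning, when the remaining
covariance `||Z||` falls below `1e-10 * sqrt(ssX * ssY)`. Regression
coefficients are `beta = W (P'W)^{-1} Q'`; cumulative explained
variance uses the orthogonality of the scores
(`SS_k = t_k't_k * ||q_k||^2`, additive across components).

The component count defaults to 10, the explained-variance plateau for
cohorts of ~40 subjects; `plateauComponents()` implements an automatic
rule (smallest k with marginal Y-variance gain below 1%) but is off by
default, keeping the fold models identical to the fixed-k design. The
"representative model" whose disease beta map is visualized is the
model refit on **all** subjects, since no single fold model is
distinguished.

For cross-validation the per-fold fit runs in Gram (subject × subject)
space: all fold quantities — the centered training Gram matrix, the
held-out subjects' centered Gram rows, and the prediction operator
`C = U_norm (P'W)^{-1} Q'` — derive from one precomputed `X X'`. This
is algebraically the same NIPALS solution (the tests assert agreement
with the direct fit to 1e-8 and with an established reference
implementation to 1e-6) but reduces a 432-fold CV on thousands of
voxels from minutes to under a second.

## Cross-validation and evaluation

Leave-one-pair-out enumerates the full Cartesian product of (BD, MDD)
pairs in lexicographic id order: 432 folds for 16/27. Per fold the
model — including centering — is recomputed from the 41 training
subjects only; the two held-out disease scores are recorded, giving 27
predictions per BD subject and 16 per MDD subject, which are averaged
per subject. Pair-wise holdout keeps every training set at the same
15/26 class composition, which plain leave-one-out would not.

ROC analysis uses the 43 per-subject means (one point per subject; a
`perFold` flag evaluates the 864 fold predictions instead). AUC is the
Mann–Whitney pair probability with ties counted ½. The confidence
interval defaults to DeLong's structural-components normal
approximation, clipped to [0, 1], because it is deterministic; a seeded
stratified bootstrap is available. The Youden threshold sweeps the
observed scores, classifies BD iff `score >= threshold` (BD is coded 1,
so higher scores mean more BD-like), and breaks ties toward the
smallest qualifying threshold. The DOI sensitivity analysis repeats the
whole CV with illness duration appended to the response block and
reports both AUCs and their signed difference; a centered constant DOI
column provably changes nothing, which the tests assert to 1e-10.

# The synthetic-cohort generator

The generator is first-class, tested code: it defines the conditions
under which every downstream claim is validated.

Each subject's volume is built as

```
smooth( baseline * (1 + site_offset) + noise ) + diagnosis * effects
```

followed by SUVR normalization (disable with `normalize = FALSE`).

* **Baseline**: a constant plus three broad Gaussian bumps — a strong
  central bump (amplitude 0.9, sigma of min(grid)/2) creating a
  gray-matter-like high-SUVR plateau around 1.2–1.4 after
  normalization, one negative pocket and one small positive bump for
  asymmetry. This makes the > 0.9 signal mask bite realistically: about
  a third of the brain survives the all-subject conjunction, and
  moderate BD-ward decreases do not push effect regions out of the
  mask, mirroring real gray matter sitting well above the whole-brain
  mean.
* **Effects** are added *after* smoothing, so that with zero noise and
  zero site offsets the group-mean difference inside each region equals
  `sign * delta` exactly — an exactly assertable ground truth. The cost
  is a spatially sharp effect edge (real effects taper); the smoothing
  still shapes baseline and noise as a scanner's point-spread function
  would. Defaults embed two opposite-signed spheres (radius 3 voxels,
  ±0.1 SUVR): an anterior "frontal" BD-lower region and a posterior
  "parieto-occipital" BD-higher region, the magnitude and topology of
  reported group differences.
* **Noise**: i.i.d. Gaussian, SD 0.5 pre-smoothing on a baseline near
  1. After the 8 mm kernel this leaves roughly 0.1 SUVR of
  between-subject voxel variability — the scale seen in real SUVR maps.
* **Sites**: four labels (the number of recruiting hospitals in the
  reference design), each with a multiplicative gain offset drawn once
  per site (SD 0.02), emulating scanner gain differences the site
  covariate should absorb.
* **Covariates** mirror the reference cohort's clinical table: ages
  near 42 ± 8 in both groups, MADRS ≥ 8 (depressive episode), YMRS ≤ 7,
  and illness duration about twice as long in BD (16.6 ± 8.6 vs
  8.8 ± 8.1 years) unless `doiDependent = FALSE` draws it independently
  of diagnosis for sensitivity experiments. Sex ratios are configurable
  (`sexProb`) rather than matched, because the published counts are
  internally inconsistent. Age and sex have no structural effect on the
  volumes by default — they are nuisance responses, not signal.
* **Determinism**: one integer seed makes cohorts bit-identical; the
  pipeline fans a master seed out to stage seeds at fixed offsets.

What the generator does **not** emulate: attenuation/scatter physics,
kinetic modeling, anatomical structure (the brain is an ellipsoid, the
"atlas" the seeded regions themselves), spatial normalization error,
motion, or partial-volume effects beyond what smoothing induces.
Passing tests therefore demonstrate the statistical machinery is
correct and calibrated under known conditions — not that clinical
accuracy would reach the same numbers.

# Validation suite: problem sizes

The package's own validation choices, chosen to exercise the study
dimensions while keeping a full run of the suite within minutes:

* Null calibration: 100 null cohorts (16/27, 24³ grid) for the CV AUC,
  which must average within 0.5 ± 0.05; 200 null replicates with 200
  permutations each for the cluster type-I rate, bounded by
  `0.05 + 3 * sqrt(0.05 * 0.95 / 200)`.
* Power: effect sizes delta in {0, 0.05, 0.1, 0.2}, 10 seeds each; the
  mean CV AUC must increase strictly, and at delta = 0.2 the disease
  beta map's mean sign inside each seeded region must match the seeded
  sign in at least 90% of cases.
* DOI stability: 10 cohorts with diagnosis-independent DOI; the mean
  absolute AUC change from adding DOI must stay below 0.05.
* PLS oracles: 50 random problems against the SVD of the centered
  cross-product and the least-squares solution; reference-implementation
  agreement (mixOmics) and ROC/DeLong agreement (pROC) are asserted in
  the unit suites.

# Design decisions and limitations

* The interface is R functions plus `runPipeline()`; there is no shell
  executable, since the package is used from R scripts and the
  reproduction script covers the batch entry point.
* `clusterFDR()` takes the voxel data (not a precomputed t map),
  because permutation calibration needs the subject-level matrix; the
  t map remains available separately through `voxelwiseTTest()`.
* Statistics and classification use different masks (gray-matter
  stand-in vs signal mask), as the method prescribes; `runPipeline()`
  stacks both.
* Voxel group tests are unadjusted two-sample comparisons; covariate
  adjustment happens only inside the PLS response block.
* The permutation/BH cluster procedure is conservative for sharp strong
  effects (see above) and its p-values are granular in `1/(B+1)`.
* Tiny cohorts can separate perfectly, collapsing the DeLong interval
  to a point (reported with a warning).
* With 43 subjects the CV AUC itself is a noisy estimate; the
  calibration suite bounds its null mean, not its variance.
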