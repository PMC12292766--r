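---
title: "Methods: coxal bone morphometrics and sex estimation with coxmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coxal bone morphometrics and sex estimation with coxmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coxmorph)
```

## The problem

The human pelvis is the most sexually dimorphic region of the skeleton, and
the coxal (hip) bone — the fused ilium, ischium, and pubis — carries most of
that signal: male bones are generally larger, while the greater sciatic notch
and the ischiopubic region are relatively wider and more open in females as an
obstetric adaptation. `coxmorph` implements a complete measurement-to-model
pipeline for estimating sex from 3D coxal bone landmarks: it converts
landmark coordinates into reproducible measurement batteries, quantifies the
observer's landmarking error, characterizes sex, side, and age effects
measurement by measurement, and trains regularized linear classifiers whose
output is a per-class probability.

The package is organized around a fixed schema of 34 named anatomical
landmarks (`landmark_registry()`). Coordinates live in an arbitrary scanner
frame in millimetres; no registration or mirroring is ever applied, because
every quantity the pipeline computes — distances, triangle heights, unsigned
angles — is invariant under rigid motion and reflection. This is a deliberate
design choice: it removes a whole class of preprocessing failure modes
(misaligned frames, inconsistent left/right mirroring) at no analytic cost.

## Measurement model

Two batteries are derived from each bone (`compute_first_dataset()`,
`compute_ild_dataset()`):

* the **standard battery** of 33 measurements — 27 linear interlandmark
  distances, 3 triangle heights (the orthogonal distance from an apex
  landmark to the infinite line through two baseline landmarks), and 3 vertex
  angles in degrees;
* the **exhaustive battery** of all $\binom{34}{2} = 561$ interlandmark
  distances (ILDs), named `a-b` in registry order.

Numerical details worth stating: the angle cosine is clamped to $[-1, 1]$
before `acos`, so collinear arms return exactly 0° or 180° instead of `NaN`;
heights use the infinite line, not the clamped segment, so an apex beyond a
baseline endpoint still projects orthogonally; degenerate geometry (coincident
vertex/arm or baseline points) raises an error rather than guessing. Angles
are reported in degrees, the natural reading of the published summary ranges
(roughly 50–156). The test suite verifies rigid-motion and mirror invariance
to 1e-9 relative and agreement of the three angles with the law of cosines to
1e-6 degrees.

## Missing-landmark imputation

CT-derived bones occasionally miss landmarks (typically parts of the ischium
outside the scanned field); the supported regime is 1–3 missing landmarks per
bone. `impute_cohort()` completes the per-side bones × 102 coordinate matrix
by iterative conditional regression: each missing scalar coordinate is
treated as a response and regressed on the other 101 coordinates, with
predictions refreshed in cycles until the largest relative change falls below
`tolerance` (default 1e-3) or `max_iterations` (default 10) is reached. The
base learner is a Bayesian ridge regression fitted by evidence maximization,
i.e. an L2-shrunk linear model whose shrinkage strength is estimated from the
data rather than fixed or cross-validated.

Choices the user should know about:

* Initial fill is the column mean; columns are visited in descending
  missing-count order. These defaults are declared, not sacred — the
  converged fixed point is insensitive to them in our tests.
* Imputation pools males and females within a side and runs before any
  train/test split. This mirrors common practice but is, strictly, a mild
  leak; with at most 3 of 34 landmarks missing on a small minority of bones
  the effect is negligible, and the split machinery operates downstream of
  it.
* Records missing more than 3 landmarks are rejected unless
  `allow_excess_missing = TRUE`; validation (`validate_cohort()`) flags them
  report-only.

## Intraobserver error (TEM / rTEM)

Landmarking precision is summarized by the technical error of measurement
over repeated acquisitions ($N$ subjects, $k$ repeats):

$$\mathrm{TEM} = \sqrt{\frac{\sum_i \left(\sum_j x_{ij}^2 -
(\sum_j x_{ij})^2 / k\right)}{N(k-1)}},$$

the square root of the pooled within-subject variance, with
$\mathrm{rTEM} = 100\cdot\mathrm{TEM}/\bar{x}$ as a percentage of the grand
mean over all $N \times k$ values (for balanced designs the grand mean and
the mean of subject means coincide; we use the grand mean).
`reliability_study()` evaluates TEM/rTEM for every ILD on each side — 1122
entries for a two-sided study — because the ILD battery either contains or
generates (via heights and angles) everything in the standard battery. Under
isotropic per-landmark acquisition noise of SD $\sigma$, the TEM of a
well-separated ILD concentrates near $\sigma\sqrt{2}$; the test suite checks
that band and the linear scaling of TEM with $\sigma$.

## Group comparisons

`compare_groups()` reproduces the per-measurement testing scheme: two-sided
tests at $\alpha = 0.05$ with **no multiple-testing correction** (the results
are descriptive per-measurement summaries, not a corrected discovery set —
users wanting FWER/FDR control should adjust the returned p-values
themselves). The parametric/rank-based choice is gated by Shapiro–Wilk
normality at 0.05: Welch's t versus Mann–Whitney U for sex and age groups,
paired t versus Wilcoxon signed-rank for right/left (gate applied to the
paired differences). We require **both** groups to pass the gate for a
parametric test; requiring only one is the other defensible reading, and on
near-normal morphometric data the two rules rarely disagree. Sex comparisons
run per side, side comparisons per sex (paired within individual, right minus
left), age comparisons per sex per side with the groups split at 45 years —
the onset-of-menopause cut-off, where hormonally driven bone remodelling can
plausibly diverge between the sexes.

Feature screening for classification keeps only measurements with a
significant sex difference. By default the screen is computed on the
**training portion** of the split; screening on the full sample (available
via the pipeline's `screen_on = "full"`) biases test accuracy upward and is
provided only for protocol replication.

## Classifiers

`tune_and_fit()` implements one protocol for three linear models: logistic
regression with L1 or L2 penalty (via `glmnet`) and a linear-kernel SVM (via
`e1071`/libsvm). All features are standardized with parameters fitted on
training data only — and refitted inside every cross-validation fold, so no
fold ever sees test statistics. The single hyperparameter $C$ (inverse
regularization strength for LR, margin–error trade-off for the SVM) is chosen
by a log-uniform random search of 50 candidates over $[10^{-3}, 10^2]$,
scored by mean accuracy under 10-repeat 5-fold stratified cross-validation,
with ties broken toward stronger regularization. The glmnet mapping is
$\lambda = 1/(nC)$, which makes the penalized objectives of the two LR
parameterizations equivalent. The reported training accuracy is the CV mean
at the chosen $C$ with a normal-approximation 95% interval over the 50 fold
scores.

Splits are drawn at the **bone** level by `stratified_split()`: 50 test bones
for single-side models (stratified by sex and age group), 100 for combined
left+right models (additionally by side), with largest-remainder allocation
so every stratum's test share is within one bone of proportional. In the
combined scope the two bones of one individual can land on opposite sides of
the boundary; bilateral asymmetry keeps them non-identical, but they remain
correlated, so combined-scope test accuracy should be read as slightly
optimistic — the pipeline replicates this design rather than silently
changing it.

SVM class probabilities come from a Platt-style sigmoid fitted to the
training decision values by logistic regression — a deterministic mapping
from the margin to a probability (libsvm's built-in calibration uses an
internally seeded CV that cannot be made reproducible from R). For LR the
decision value is already a log-odds and is passed through the logistic
function directly. Models persist as RDS plus a JSON sidecar, and a
save/load round trip reproduces predictions bit-identically.

`rfecv_select()` provides recursive feature elimination with
cross-validation: within each of 5 folds, features are dropped one at a time
by lowest impurity importance from a 100-tree random forest (`ranger`)
fitted on the fold's training part, held-out accuracy is recorded at every
feature count, and the count maximizing mean CV accuracy (smallest on ties)
is reproduced by a final elimination pass on the full training set.

## Synthetic cohorts

No raw landmark data ship with the package, so the generators are the
pipeline's test bed. They are calibrated to published summary statistics of a
cohort of 276 adults (136 males, 140 females; sex-specific truncated-Gaussian
age models: males 56.5 ± 14.8 years on [19, 83], females 56.7 ± 13.8 on
[19, 88]); the presets (`table2_preset()`, `table3_preset()`,
`table4_preset()`) are transcribed sex/side means and SDs for all 33
measurements, right-minus-left offsets, and young-minus-old offsets. Two
levels exist because the true covariance of the source data is unpublished:

* **Measurement-level** (`generate_measurement_cohort()`): multivariate
  Gaussian per sex and side with the preset means/SDs and an exchangeable
  correlation $\rho = 0.3$ among linear/height measurements ($\rho/2$ for the
  angle block; the matrix is checked for positive definiteness and $\rho$
  shrunk if needed). 0.3 is a deliberately moderate stand-in for the strong
  but heterogeneous size correlations of real bones. For two-sided cohorts,
  each individual's bones share a latent vector centred on the mid-side mean;
  the published right-minus-left offsets are split $\pm d/2$ across the
  sides, and 10% of the variance is independent side noise, so paired tests
  see both a systematic offset and within-pair correlation.
* **Landmark-level** (`generate_landmark_cohort()`): bones are deformed
  copies of sex/side **calibrated templates** — a global scale factor
  $\mathcal{N}(1, 0.03^2)$ shared by an individual's two sides plus 1.5 mm
  isotropic per-landmark jitter — with optional masking of 1–3 landmarks on a
  configurable number of bones (the emulated cohort rate is 35 of 552) and
  optional repeated acquisitions at 0.3 mm noise for reliability studies.
  Here cross-measurement correlation arises geometrically from shared
  landmarks and shared scale.

A calibrated template (`calibrate_template()`) is a 34×3 configuration whose
derived 33 measurements match a target mean vector to within 1% relative. It
is found by Levenberg–Marquardt least squares over the 102 coordinates from a
hand-built anatomical starting layout, with a weak anchor toward that start
(weight 1e-6, which also pins the six rigid-motion gauge directions) and a
hinge penalty keeping all pairwise landmark distances above 10 mm — short
pairs would make relative error statistics (like rTEM) explode for reasons of
arithmetic, not anatomy. Achieved residuals are typically below 1e-4
relative, and the fit is deterministic.

The generators reproduce what they are calibrated to — means, SDs, laterality
offsets, dimorphism signs (including the four female-larger measurements:
greater sciatic notch breadth and angle, ischiopubic ramus length, posterior
interspinal height) — and *only* that. They do not reproduce the real
covariance structure, non-Gaussian tails, measurement-specific asymmetry
variance, or population substructure. Classification accuracy on these
cohorts therefore validates the protocol (screening, scaling, tuning,
splitting, evaluation) rather than estimating field performance on real
bones.

One transcription note: the published age-difference table labels its column
as the younger-minus-older difference while the surrounding text describes
most measurements as larger in the older group; the shipped preset follows
the printed label literally (the over-45 group is shifted by $-d$). Age
offsets are off by default and nothing downstream depends on their sign.

## Problem sizes and determinism

Default analyses run at the emulated cohort scale (276 individuals, 552
bones); distribution-level checks use 10,000-bone samples, and reliability
studies 30 subjects × 2 sides × 3 acquisitions, sizes at which the Monte
Carlo error of the checked quantities is well below their tolerance. Every
stochastic stage takes an explicit seed; `run_pipeline()` derives per-stage
seeds from one global seed and records an order-stable hash of all numeric
artifacts in its manifest, so a rerun with the same configuration is
verifiably identical.

## Known limitations

* The classifiers are linear by design (the published protocol's scope);
  nothing in the data model prevents plugging the measurement tables into
  other learners.
* Landmark-level realism is limited to scale-plus-jitter deformations of a
  calibrated template; real shape variation is anisotropic and regionalized.
* The imputer assumes approximate joint linearity of the coordinate columns,
  which holds well for jittered-template cohorts and approximately for real
  bones with few missing landmarks.
* Combined-scope evaluation inherits the bone-level split caveat described
  above.
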