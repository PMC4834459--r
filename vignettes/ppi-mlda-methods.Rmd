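---
title: "Classifying groups from PPI maps with maximum-uncertainty LDA: models and methods"
author: "ppiMLDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying groups from PPI maps with maximum-uncertainty LDA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiMLDA)
```

## The problem

Group-level fMRI analyses can show that a connectivity signature differs
between populations, but they cannot say whether that signature identifies
*individuals*. ppiMLDA implements the multivariate pattern-analysis pipeline
that turns a seed-based connectivity contrast into an individual-level
classifier: per-subject psychophysiological-interaction (PPI) t-maps are
masked to gray matter and fed to a regularized linear discriminant, whose
out-of-sample behavior is estimated by leave-one-subject-out
cross-validation (LOOCV). The motivating application is detecting
vulnerability to major depression from guilt-selective functional
disconnection of the right superior anterior temporal lobe (ATL): remitted
patients versus never-depressed controls, with the ATL seed taken as a 4 mm
sphere at MNI (58, 0, -12), gray matter defined by tissue probability
strictly above 0.25, and the top 1% most discriminative voxels entering the
final discriminant.

Because the underlying patient data are not publicly deposited, the package
ships a first-class synthetic-data generator that emulates the study's
acquisition geometry and implants a known, sparse multivoxel group
difference. Every stage of the pipeline is therefore testable end-to-end
against ground truth.

## The PPI first-level model

For each subject, runs are concatenated and each voxel's time series is
modeled as

$$ y(t) = \beta_p\, p(t) + \beta_s\, s(t) + \beta_{sp}\, [s(t)-\bar s][p(t)-\bar p] + \text{run intercepts} + \varepsilon(t), $$

where $p(t)$ is the psychological regressor (condition boxcars weighted
guilt $+1$, indignation $-1$, baseline $0$, convolved with the canonical
double-gamma HRF, sampled at acquisition times and mean-centered), $s(t)$ is
the seed's mean BOLD series, and the interaction is the elementwise product
of the mean-centered pair (centering per run). The contrast of interest is
the interaction coefficient; its voxelwise $t$ statistic

$$ t = \frac{c^\top\hat\beta}{\sqrt{\hat\sigma^2\, c^\top (X^\top X)^{-1} c}},
   \qquad \hat\sigma^2 = \mathrm{RSS}/(n - \mathrm{rank}\,X), $$

forms the subject's PPI map. A `physio` contrast on $\beta_s$ implements the
specificity control: seed coupling irrespective of psychological context.

Three modeling choices deserve explicit mention:

* **No neural-level deconvolution.** SPM-style PPI deconvolves the seed
  series to the "neural" level before multiplying. The deconvolution is
  ill-posed, its regularization parameters are rarely reported, and at
  TR = 2 s the BOLD-level product is a close surrogate; the package forms
  the interaction at the BOLD level from the centered series. This is a
  known divergence from the SPM pipeline and is the package's own,
  documented convention.
* **HRF.** The canonical double-gamma (peak 6 s, undershoot 16 s, ratio
  1/6, 32 s kernel, 0.1 s internal resolution). Parameters are exposed in
  `hrfSpec()`.
* **Confounds and filtering.** None by default: per-run intercepts only.
  `assemblePPIDesign()` accepts arbitrary confound regressors; whether the
  original analysis used any is unknown, so the default is the minimal
  model.

Numerically, the GLM is solved by QR per subject for all voxels at once.
Voxels whose residual sum of squares is zero up to a relative tolerance of
$10^{-12}$ (e.g. noise-free simulations) are flagged and given signed
infinite $t$ rather than raising an error.

## Maximum-uncertainty LDA

With $p$ voxels and only tens of subjects, the pooled within-class
covariance $S_p$ (unbiased, denominator $n-2$) is massively rank-deficient.
The maximum-uncertainty (maximum-entropy) regularization replaces every
eigenvalue of $S_p$ below the average by the average:

$$ S_p = \Phi \Lambda \Phi^\top, \qquad
   \bar\lambda = \mathrm{tr}(S_p)/p, \qquad
   \lambda_i^* = \max(\lambda_i, \bar\lambda), \qquad
   S^* = \Phi \Lambda^* \Phi^\top, $$

and the discriminant is $w = S^{*-1}(\mu_1 - \mu_2)$ with bias
$b = -w^\top(\mu_1+\mu_2)/2$, so the decision value $z(x) = w^\top x + b$ is
positive on the patient side of the midpoint between class means. Because
all zero eigenvalues are raised to $\bar\lambda$, $S^*$ is always
invertible without any tunable shrinkage parameter — the classifier's only
free setting is the selection fraction.

`fitMLDA()` never forms the $p \times p$ matrix. Writing $V$ for the
orthonormal basis of the nonzero-eigenvalue subspace (rank $\le n-2$,
obtained from the $n \times n$ Gram matrix of the within-class-centered
data),

$$ S^{*-1} = \tfrac{1}{\bar\lambda}\,(I - V V^\top) + V\,\mathrm{diag}(1/\lambda_i^*)\,V^\top , $$

so the fit is $O(n^2 p)$. The test suite verifies this subspace route
against a literal dense-matrix implementation over hundreds of random
instances to $10^{-8}$ relative error.

Two conventions were genuinely open and are configurable:

* **The average eigenvalue.** $\bar\lambda = \mathrm{tr}(S_p)/p$ (mean over
  all $p$ eigenvalues, zeros included) is the default; the mean over the
  nonzero spectrum only (`lambdaBarMethod = "nonzero"`) is offered because
  the phrase "maximum entropy criterion" does not pin the denominator down.
  The choice is recorded in every fitted model and emitted report.
* **Feature ranking.** Voxels are ranked by $|w_j|$ of a full-feature MLDA
  fit on the training data — the same quantity the published weight-vector
  maps display — with exact ties broken by ascending voxel index for
  reproducibility. Univariate $|t|$ ranking (`ranking = "t"`) is available
  as an alternative. The top $\lceil \text{fraction} \cdot p \rceil$ voxels
  are kept (default fraction 0.01).

## Cross-validation and leakage

`loocvMLDA()` refits *everything* — feature selection included — inside
each fold, so the held-out subject never influences which voxels enter the
model. Whether the original analysis nested its selection is not stated in
the source material; nesting is the defensible default and is flagged in
the emitted metrics (`selection_nested_in_folds`). Predictions use the
fixed threshold $z > 0$; there is no cost or probability calibration.

## Evaluation statistics

* Confusion counts with patients as the positive class; accuracy,
  sensitivity, specificity.
* ROC by sweeping $z > \tau$ over the unique decision values; AUC computed
  exactly as the midrank Mann-Whitney statistic
  $P(z_\text{patient} > z_\text{control}) + \tfrac12 P(\text{tie})$, and
  verified against trapezoidal integration of the curve to $10^{-12}$.
  Constant decision values yield AUC 0.5 with a warning record.
* Exact one-sided binomial tail against chance ($p_0 = 0.5$; detection
  above chance is the directional hypothesis — stated in the report
  metadata).
* Pearson correlation between decision values and a covariate (severity
  scores), $t$-transform p-value, pairwise NA deletion with a logged count.
* Rank-sum comparison between subgroups (e.g. medicated vs medication-free
  patients): the report prints both the Mann-Whitney $U$ of the first
  subgroup and its raw rank sum, since software conventions differ; exact
  p-value for small untied samples, normal approximation with tie and
  continuity correction otherwise.
* A chi-square test on the 2x2 confusion table is reported under its own
  name; it is *not* claimed to reproduce any unspecified published test.

## The synthetic generator

`generatePPIMaps()` emulates the *output* of the first level: per subject,
an i.i.d. Gaussian field smoothed with a separable Gaussian kernel
($\sigma_\text{axis} = \mathrm{FWHM}/(2\sqrt{2\ln 2})/\text{voxel size}$,
truncated at $4\sigma$, zero-padded), then standardized to unit variance
per voxel. The standardization uses the *exact* per-voxel standard
deviation implied by the truncated kernel and the zero padding (a
convolution of a ones-field with the squared kernel taps), not a single
interior-voxel factor, so the realized standardized group difference equals
`effectSizeD` at edge voxels too. Patients then receive a mean shift of
`effectSizeD` at the truth voxels.

`generateTimeseriesCohort()` emulates the *input* instead: seed series =
HRF-convolved task drive + AR(1) noise; every voxel follows the PPI
generative model above with the interaction coefficient reduced in patients
at truth voxels only (`betaPpiControl = 0.5`, `betaPpiPatient = 0` — the
implanted guilt-context-selective disconnection) and identical coefficients
elsewhere, plus AR(1) noise. The `physio` control contrast therefore
carries no group signal by construction, reproducing the mechanism behind
a chance-level control classification.

Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| TR, volumes, runs | 2 s, 400, 3 | the emulated acquisition |
| voxel size | 2.29 x 2.29 x 3 mm | the emulated acquisition |
| smoothing FWHM | 6 mm | the emulated preprocessing |
| cohort | 25 patients / 21 controls | the emulated cohort |
| `signalFraction` | 0.01 | matches the 1% selection scale |
| `nClusters` | 4 | discriminative voxels form a few contiguous regions, as in published weight maps, not scattered singletons |
| `effectSizeD` | 1.2 | a moderate per-voxel multivoxel effect, the size a between-group MVPA study of ~46 subjects could plausibly carry; chosen once |
| `noiseAr1` | 0.3 | minimal temporally correlated noise model; typical lag-1 BOLD autocorrelation at TR 2 s |
| grid | 20 x 24 x 20 | a reduced patch keeping a full cohort analysis at seconds scale; full-size grids via `gridShape` |
| events | 30 per condition/run, <= 5 s, jittered ITI | the emulated event-related design; exact timings are not printed anywhere, so schedules are configurable |

Determinism: all generators run under a locally seeded RNG
(`rngSeed`), restore the caller's RNG state, and regenerate bit-identical
cohorts — serialized outputs included.

What the generator does **not** emulate: anatomy (the gray-matter map is a
smooth random probability field), scanner artifacts, motion, physiological
noise, spatial covariance structure beyond stationary smoothing, or
between-subject variability in the HRF. Passing tests therefore demonstrate
that the *pipeline machinery* is correct and calibrated under its stated
assumptions — not that the headline accuracies would be attained on real
patient data.

## Numerical choices and degenerate inputs

* Gray-matter masking is strictly `> 0.25`; voxels exactly at the
  threshold are excluded. Feature order is ascending linear voxel index
  (x fastest), recorded alongside every feature matrix so that weight maps
  back-project exactly.
* Eigenvalues below `max(eigenvalue) * 1e-12` of the Gram matrix are
  treated as zero (rank detection).
* `fitMLDA()` requires both classes non-empty and $n \ge 3$; LOOCV requires
  $n \ge 4$ and two subjects per class, so folds of the minimal cohort
  degrade to singleton classes, which the pooled covariance (denominator
  $n-2$) handles.
* ROI membership is by voxel-center Euclidean distance in world
  coordinates, with a $10^{-9}$ mm$^2$ tolerance on the squared radius so
  exactly-on-the-sphere centers are included; a sphere center outside the
  grid is an error.
* Rank-deficient designs raise an error naming the collinear columns.
* The NIfTI-1 sform is float32 by format; affines round-trip exactly when
  float32-representable and to ~$10^{-7}$ otherwise. Voxel data are written
  as doubles and round-trip bit-exactly.

## Properties of the LOOCV estimator

Leave-one-out folds share all but one training subject, so the per-subject
predictions are positively correlated and the spread of the accuracy
estimate is wider than the binomial standard error
$\sqrt{0.25/n}$ would suggest; mean-based classifiers also show the
well-known slight below-chance bias of LOOCV accuracy on null data. The
package's calibration simulations (null cohorts, `effectSizeD = 0`) exhibit
both effects: the null accuracy distribution is centered just below 0.5
with roughly 1.5x the binomial width. Users comparing a LOOCV accuracy
against chance should rely on the exact binomial test *as a significance
screen for a single observed split* (its published use) while remembering
that the LOOCV accuracy itself is not a binomial draw; permutation of
labels is the more faithful reference distribution when compute allows.

## Problem sizes used by the test suite

The suite exercises full cohorts (46 subjects, ~7,000 in-mask voxels) for
classification tests, reduced grids (about 10 x 10 x 8, 80-120 volumes,
1-2 runs) for time-series tests, and 20-seed replications for calibration
and recovery properties; these sizes were chosen so that the complete suite
documents the pipeline's statistical behavior while remaining a
desk-runtime check.
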