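---
title: "Chromatin packing scaling from csPWS microscopy: models and methods"
author: "cspws maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin packing scaling from csPWS microscopy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cspws)
```

## The measurement and its model

Chromatin-sensitive partial wave spectroscopic (csPWS) microscopy records,
for every pixel of a cell image, the back-scattered interference spectrum
over visible wavelengths (here 500-700 nm in 2 nm steps), normalized by a
reference wave. Sub-diffractional spatial fluctuations of chromatin density
modulate that spectrum, and their strength is summarized by Sigma, the
standard deviation of the (detrended) normalized spectrum over wavelength.

Inside supranucleosomal packing domains, chromatin mass scales with domain
radius as a mass fractal, \(N_f \propto r^D\), so the spatial
autocorrelation function (ACF) of mass density follows a power law whose
log-log slope is \(D - 3\) within the length-scale window the instrument is
sensitive to (about 23-334 nm for the modeled numerical apertures of
0.6/0.8). The forward model connecting the two is

\[
\Sigma^2(D) \;=\; A\,\phi(1-\phi)\,\ell_z
  \int_{r_{min}}^{r_{max}} B_D(r)\, S(r)\, r \, dr,
\qquad B_D(r) = (r/r_{min})^{D-3},
\]

with \(\phi\) the chromatin volume concentration, \(S(r)\) a Gaussian
transverse coherence kernel of scale 458 nm, \(\ell_z\) the axial depth of
field (~3 um), and \(A\) an instrument constant. Two modelling choices
deserve emphasis:

* **Normalization of the power law at \(r_{min}\).** Normalizing the
  windowed ACF at the lower sensitivity bound makes \(\Sigma(D)\) strictly
  increasing in \(D\), which matches the physical picture (denser long-range
  packing produces stronger density fluctuations at the probed scales) and
  is what makes the table invertible. Normalizing at \(r_{max}\) instead
  would reverse the monotonicity.
* **Self-consistent absolute scale.** The constant \(A\) is fixed by a
  normalization convention (\(\Sigma(2.5) = 0.02\) by default). Absolute D
  values produced by this package are therefore defined by its own forward
  model, not cross-calibrated against any physical instrument or electron
  microscopy ground truth. Group differences, effect sizes, slopes, and
  classifier performance - the quantities the analyses consume - are
  invariant to this convention.

`estimateDMap()` inverts the tabulated, strictly monotone Sigma(D) by linear
interpolation. Sigma values outside the table clamp to the nearest end and
are flagged (never extrapolated); clamped pixels are excluded from nuclear
averages, and a clamp fraction above 50% raises a warning. Because white
measurement noise adds its variance to Sigma^2, a known noise floor can be
subtracted in quadrature before inversion; this is what keeps the noisy
round-trip error below 0.05 D units at a noise SD of 0.01.

## The synthetic-data generator

No public csPWS data exist, so every analysis stage is exercised against a
generator whose defaults encode the modeled screening study:

* **Density fields.** `sampleDensityField()` draws stationary Gaussian
  random fields whose ACF follows the windowed power law. A strict windowed
  power law is not positive definite, so the generator uses a realizable
  surrogate: a mixture of Gaussian correlation kernels with log-spaced
  scales, whose weight exponent is calibrated by root finding so that the
  *expected value of the empirical estimator* (binned radial ACF of a
  mean-subtracted field, including its mean-subtraction bias) has log-log
  slope exactly \(D-3\) over the window. As \(D \to 3\) a perfectly flat
  windowed ACF is also not realizable; the target slope is capped just
  below zero, which is well inside the +/- 0.1 recovery tolerance.
* **Spectra.** `simulateSpectralCube()` synthesizes each pixel's spectrum
  as 1 + Sigma * z(lambda) + noise, where z is a unit-variance fluctuation
  process orthogonal to a linear baseline. The detrended spectral SD
  therefore reproduces the forward map *exactly* at zero noise, and noise
  adds its variance on top. Spectra are a calibrated stochastic process,
  not an electromagnetic simulation: cube-level D recovery tests the
  plumbing and the inversion, while physical realism of the density
  statistics is tested separately at the field-ACF level.
* **Nuclei.** `synthesizeNucleusImage()` places an elliptical nucleus on a
  near-quiet background (2% of the nuclear Sigma). Intra-nuclear D
  heterogeneity is drawn as a correlated random field whose ACF exponent is
  the nucleus's own D - a self-similarity assumption under which both the
  level and the spatial texture of a D map carry class information, as they
  do in real csPWS maps.
* **Cohorts.** `generateCohort()` draws 256 patients split
  135/13/15/74/9/10 across control, diminutive adenoma, nondiminutive
  adenoma, advanced adenoma, HNPCC, and cancer, with at least 31 cells per
  patient. Cell-level truth is
  \(D = \bar D_{group} + \delta_{history} + slope_{age}(age-\overline{age})
  + b_{patient} + e_{cell}\).
  Because no absolute group D values are published, the group means
  (2.50 control to 2.74 cancer) are placeholders on the package's internal
  scale; the advanced-adenoma vs control gap (0.14) and between-patient SD
  (0.08) were chosen once so that the *realized* patient-level Cohen's d
  for advanced adenoma vs control is about 0.8 - the reported range of
  risk-history effect sizes - after accounting for the variance the age
  slope induces (cases average ~7 years older). The age coefficient
  defaults to -0.008 D units per year; the history shift (0/0.03/0.06 for
  no/low/high-risk history) encodes that mucosa-wide chromatin changes
  track past findings as well as current ones. Demographics use the
  published per-group age means and covariate rates. All randomness flows
  from one seed through deterministic child seeds, so identical
  configurations produce byte-identical manifests.

What passing tests on these data do **not** show: robustness to staining
and debris artifacts, instrument drift, segmentation of touching or folded
cells, absolute-D transfer across instruments, or any property of real
patient cohorts. The generator emulates statistical structure, not imaging
physics.

## Cohort statistics

Group comparisons use Welch's t-test on patient-mean D (the two-group test
is not standardized in this field; a pooled-SD Cohen's d is reported with
the sign convention case minus control). The confounder screen is a linear
model of patient mean D on a case indicator (nondiminutive adenoma +
advanced adenoma + cancer) plus age, sex, smoking, and drinking; raw
p-values are reported without multiplicity adjustment, and that choice is
recorded in the report. `ageRegression()` defaults to including diagnostic
group as a fixed effect so the age coefficient is estimated within groups;
without that adjustment the older case mix would confound the estimate.
The univariate screening analysis stratifies a 50/50 split by class,
derives the optimal cutpoint on the development half, and reports rank AUC,
sensitivity, and specificity on the testing half.

## The 5-year risk model

Population risk is the printed formula
\(\frac{1}{N_a+N_c}\left[AA_r \sum_i AA{\to}CRC_i + N_c\,CRC_m\right]\),
with the annual advanced-adenoma-to-CRC rate stratified by sex and by age
below/at-or-above 80 years and converted to cumulative form by
\(1 - e^{-rate \times time}\). The literature-derived rates are
configuration, not estimates: the defaults are placeholders of plausible
magnitude and any substantive analysis should supply its own. Two
documented conventions extend the printed formula to cohort populations:
AAr enters once per population (the patient mean of per-patient values),
and each patient's future-AA probability composes the history route and the
current-finding route as independent risks,
\(AA_r = 1-(1-AA_r^{hist})(1-AA_r^{current})\), without which populations
defined by current advanced adenoma could not exceed high-risk-history
controls.

## The AI classification pipeline

Per-cell D maps are cropped to the nucleus, min-max scaled inside the mask
(constant nuclei map to 0.5 by convention), zero-filled outside, resized
anisotropically to the backbone input, and replicated to three channels.
Features come from a pluggable backbone; the default is a fixed-seed
random-weight convolutional network (3x3 stride-2 stages, ReLU, global
average pooling) whose frozen random filters preserve multi-scale texture
statistics while keeping the pipeline fully reproducible and offline. A
pretrained deep network can be plugged in through `customBackbone()`; an
identity-downsample baseline is also provided. Features are compressed by a
5-layer encoder / 5-layer decoder autoencoder (tanh hidden layers, linear
latent and output, geometric width taper, full-batch Adam, 50 epochs,
40-dimensional code) and classified by a random forest whose ntree/mtry/
nodesize are grid-searched by inner stratified cross-validation on training
data only.

Evaluation is repeated stratified fourfold cross-validation with five
repeats (20 folds). Stratification is at the *patient* level - every cell
of a patient stays on one side of each split - because per-cell splitting
would leak patient identity into validation scores. Within each fold the
autoencoder, the grid search, and the forest see training cells only
(audited by recorded index sets); validation cells are scored, scores are
averaged per patient, and AUC plus optimal-cutpoint sensitivity/specificity
(correct-classification count maximized, ties toward higher sensitivity
then lower threshold) are computed on validation patients. Summaries are
means +/- SD over the 20 folds.

## Numerical choices and problem sizes

Quadrature uses `stats::integrate` at rel.tol 1e-8; table inversion is
linear interpolation on a 0.01-spaced D grid; Sigma detrending defaults to
polynomial order 1 with an unbiased residual variance denominator. The test
suite and the acceptance script size their simulations for a single CPU:
ACF recovery on 512^2-1024^2 grids, round trips on 40^2-100^2 nuclei,
classification on a 24-patient, 744-cell strong-signal cohort with 32 px
inputs and a 48-feature backbone, and an 8-patient end-to-end pipeline run.
These sizes were chosen as the smallest at which the tested tolerances are
comfortably stable.

## Known limitations

Absolute D is internally defined (no ChromTEM/FDTD cross-calibration);
fields are 2D projections rather than 3D volumes; spectra are stochastic
surrogates; segmentation is a global-threshold stand-in for expert
outlining; risk-model rates are placeholders; and the paper-scale
diagnostic numbers (univariate AUC 0.85, AI AUC 0.90) pertain to a private
cohort that cannot be reconstructed - the package's cohort-level outputs
are internally consistent emulations, not reproductions of those values.
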