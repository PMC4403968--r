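---
title: "Models and methods for multi-centre diffusion MRI reproducibility"
author: "dwirepro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for multi-centre diffusion MRI reproducibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwirepro)
```

This vignette documents the models implemented by `dwirepro`, the
assumptions and conventions behind them, the numerical choices that a
user may want to audit, and the limits of what the package's synthetic
data can demonstrate.

## Signal models

**Mono-exponential (ADC).** A trace-weighted diffusion signal is modelled
as `S(b) = s0 * exp(-b * ADC)`. `fitADC()` estimates the ADC as the
negative slope of an unweighted ordinary least-squares line through
`(b, ln S)`. The `b = 0` intercept is *fitted*, not pinned to the
measured `b = 0` signal: with noisy data the measured `s0` is one more
noisy observation, and treating it symmetrically makes the two-point case
reduce exactly to the closed form `ln(s0/sb)/b` while the multi-point
case gains robustness. Repeated measurements at the same b-value are
averaged before fitting; non-positive magnitudes (possible after noise
subtraction or in background voxels) are excluded from the log, and a
voxel with fewer than two usable b-values is flagged invalid rather than
raising an error, so a volume fit completes and reports a count instead
of aborting on its worst voxel.

**Bi-exponential IVIM.** Perfusing tissue adds a fast pseudo-diffusion
compartment:

$$S(b) = s_0\,[\,f\,e^{-b D^*} + (1-f)\,e^{-b D}\,]$$

with tissue diffusion coefficient $D$, pseudo-diffusion coefficient
$D^* \ge D$ and perfusion fraction $f \in [0,1]$. Direct four-parameter
fitting of clinical-quality data is ill-conditioned, so `fitIVIM()` uses
the segmented (stepwise-sequential) approach: step 1 estimates $D$ by
OLS on `ln S` versus `b` using only `b >= 300` s/mm², where the fast
compartment has largely decayed; step 2 minimises the untransformed
residual sum of squares over $(f, D^*)$ with $D$ fixed, by Nelder–Mead,
with $s_0$ fixed at the mean measured `b = 0` signal.

Numerical choices in step 2:

* **Bounds by transform.** $f = \mathrm{plogis}(\theta_1)$ and
  $D^* = D + (1 - D)\,\mathrm{plogis}(\theta_2)$ keep the simplex
  unconstrained while enforcing $f \in [0,1]$ and
  $D^* \in [D, 1]$ mm²/s.
* **Initialisation.** $f_0 = 1 - e^{\hat c}/s_0$ (the step-1 intercept
  deficit, the standard segmented estimate of $f$), clamped to
  $[0.01, 0.5]$; $D^*_0 = 10 D$.
* **Convergence.** Relative tolerance `1e-8`, at most 2000 iterations;
  non-convergence returns the best point with `converged = FALSE`.

**Why the two steps are iterated.** At the `b = 300` threshold the fast
compartment is not exactly zero: for $f = 0.1$, $D^* = 10^{-2}$ mm²/s
about 0.7% of the weighted signal at the threshold is still
pseudo-diffusion, which biases the step-1 $D$ by up to ~2.5% (brute-force
scan over $f \le 0.15$, $D \in [0.5, 1.0]\times10^{-3}$). `fitIVIM()`
therefore repeats the pair of steps, re-estimating $D$ on the
perfusion-corrected high-b signals $S - s_0 f e^{-bD^*}$, until the
parameters are stable to `1e-10` relative (at most 25 passes,
`maxRefine = 0` recovers the plain two-step estimate). On noiseless data
the iteration converges to the exact generating parameters; once the
fast compartment truly is negligible at the threshold
($D^* \gtrsim 0.02$ mm²/s with these b-values) the plain two-step $D$ is
already within 0.2% and the iteration changes essentially nothing.

**Diffusion tensor.** `fitTensor()` solves the linearised model
`ln(S/S0) = -b g' D g` by unweighted least squares over all measurements
(each gradient direction kept; the `ln S0` intercept estimated jointly).
Unweighted log-linear LS is the long-standing default of the standard
DTI tools; weighted variants are deliberately not implemented. A design
matrix of rank below 7 (fewer than six non-collinear directions plus a
`b = 0`) is a configuration error and is reported as such. Eigenvalues
are returned sorted descending and unclamped; FA is computed after
clamping negatives to zero (`clamped` records that this happened):

$$\mathrm{MD} = \bar\lambda, \qquad
\mathrm{FA} = \sqrt{\tfrac{3}{2}}\,
\frac{\sqrt{\sum_i (\lambda_i - \bar\lambda)^2}}{\sqrt{\sum_i \lambda_i^2}}$$

with FA defined as 0 for an all-zero tensor.

## Noise model

`addRicianNoise()` implements two-channel magnitude noise:
`sqrt((s + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma^2)`. Magnitude MR
images have a rectified noise floor — at zero true signal the output is
Rayleigh with mean `sigma * sqrt(pi/2)`, not zero — and this floor is what
drives the apparent FA and perfusion fraction of an isotropic,
non-perfused phantom above zero at low SNR. Gaussian noise would not
reproduce either bias, which is why the package does not offer it.
`sigma = 0` is exactly the identity, and every call requires an explicit
seed: there is no hidden global RNG state anywhere in the simulators, and
all sub-streams are derived deterministically from one master seed so
that adding a pipeline stage never shifts the draws of another.

## The synthetic study

**Phantom.** `simulatePhantom()` builds five water tubes at the ice-water
reference diffusivity `1.099e-3` mm²/s — an ice-water bath pins the
temperature at 0 °C, making this a portable diffusion standard — plus one
sucrose tube, default diffusivity `0.5e-3` mm²/s (sucrose solutions
diffuse slower than free water and appear darker on ADC maps; the exact
value is configurable and nothing downstream depends on it). Tubes are
label-pure: each voxel is entirely water, sucrose or background. Real
phantoms add partial-volume rims, susceptibility artefacts and
temperature gradients; a passing phantom round-trip therefore validates
the estimator chain, not robustness to those effects.

**Volunteer study.** `replicaStudyDesign()` encodes the study layout the
package replicates: eight scanners (A, B, D, G at 1.5 T; C, E, F, H at
3 T) sharing nine volunteers, between four and eight volunteers per
scanner, and repeat sessions (two volunteers rescanned on A, B, F, G, H;
one on C, D, E), totalling 65 imaging sessions. The published account
constrains the totals but not the exact per-scanner assignment, so the
replica uses volunteer counts (8, 7, 6, 6, 6, 7, 6, 6); any layout
consistent with the totals would serve. `simulateStudy()` then draws, per
metric and region,

$$y_{ijk} = \mu + \alpha_i + v_j + \varepsilon_{ijk}$$

with fixed scanner offsets $\alpha_i$, volunteer effects
$v_j \sim N(0, \sigma_{vol}^2)$ shared across that volunteer's sessions,
and session residuals $\varepsilon \sim N(0, \sigma_{res}^2)$. The
default grand means and volunteer/residual SDs are the published grey-
and white-matter values for ADC, D, f, MD and FA (diffusivities in
10⁻³ mm²/s); scanner offsets are drawn once per design with per-metric
SDs matching the published inter-scanner SDs (GM/WM average). Scanner
effects are *additive on the metric scale* in this table-level simulator
— the simplest mechanism consistent with a fixed effect; the image-level
phantom pipeline instead perturbs the ground-truth diffusivity per
scanner, so both interpretations are exercised. Scanner G receives double
image-noise sigma (40 vs 20 at `s0 = 1000`), a one-knob emulation of the
high-resolution, low-SNR acquisition that inflated its perfusion-fraction
estimates; no separate mechanism is modelled. The IVIM default
$D^* = 10^{-2}$ mm²/s is a free choice — fitted $D^*$ values are rarely
reported and none were available to anchor it — sitting in the range
typically quoted for brain micro-circulation.

What the generator does **not** emulate: partial-volume mixing at tissue
boundaries (only label-pure voxels), T1/T2 relaxation weighting of the
perfusion fraction, eddy-current or EPI distortion, registration error,
and session-level drifts beyond the residual term. Passing
variance-recovery tests therefore show the statistical machinery is
correct, not that real multi-centre data meet its assumptions.

## Region-of-interest conventions

* Probability maps are thresholded at 0.95 with **strict** `>` — the
  boundary probability is excluded; the published account does not state
  `>` versus `>=`, so the choice is documented here and in the function.
* Mask erosion uses a 6-connected (face-adjacent) structuring element by
  default — the most conservative standard choice, since "one voxel" does
  not specify connectivity — configurable to 26. Out-of-bounds voxels
  count as background, so the image border always erodes. Erosion exists
  to keep partial-volume rim voxels out of ROI means; the test suite
  demonstrates on synthetic contaminated rims that eroded means are
  strictly closer to truth.
* `roiMean()` skips sentinel (`NA`) voxels from invalid fits and reports
  the contributing voxel count; an empty region yields a missing value
  with count 0, and `buildMeasurementTable()` drops such rows with a
  logged warning instead of fabricating zeros — mirroring how failed
  segmentations are excluded from study tables.
* Registration is deliberately out of scope: synthetic masks live on the
  image grid, and real-data users must supply co-registered maps.

## Variance components and reporting

`fitVarianceComponents()` fits `value ~ 0 + scanner + (1 | volunteer)` by
REML — the default of the mixed-model software this field uses — and
summarises it with conventions chosen to match how such studies tabulate
results:

* $\sigma_{inter}$ is the **sample SD (n−1)** of the estimated scanner
  means, and $\mu$ their **unweighted** mean. Both conventions reproduce
  the published phantom "overall" row exactly from its per-scanner means
  and treat scanners symmetrically under unbalanced volunteer counts.
* $\sigma_{volunteer}$ is the random-effect SD; when its REML estimate
  collapses to the zero boundary (below `1e-8` of the residual SD) it is
  flagged not estimable and rendered "NE". With a truly zero volunteer
  variance the boundary is hit in roughly half of replicates — the
  asymptotic boundary probability of a variance component is 1/2 — so
  "NE" should be read as "no evidence of volunteer variance", not proof
  of its absence.
* Repeat sessions are additional observations within the (scanner,
  volunteer) cell; no session-level random term is added, matching the
  three-component description of the model.
* Data whose two-way fixed-effects fit leaves numerically zero residual
  bypass REML entirely and use the exact deterministic limit (REML on
  zero-variance data is numerically fragile and the limit is closed
  form).
* CVs are `100 * sigma / mu` with the mean fixed at the model estimate.
  Report rendering rounds CVs to one decimal and ICCs to two; internal
  values are never rounded. The minimum-detectable-change column is
  `2 * CV_inter`: a change should exceed two inter-scanner SDs before it
  is attributed to anything but scanner variability.
* On balanced designs the REML components coincide with the closed-form
  balanced-ANOVA method-of-moments estimates; the test suite asserts
  agreement to `1e-6` relative against an independently coded oracle.

Field-strength subgroup analysis refits the model within each field
strength and combined; a subgroup with fewer than two scanners cannot
identify a scanner effect and is returned flagged rather than silently
dropped. Field strength is analysed by stratification, not as a model
term — with four scanners per stratum there is too little replication to
estimate a field-strength effect inside the mixed model.

## Bundled reference tables

`volunteerSummary()` and `phantomScannerMeans()` ship the printed
per-region and per-scanner summary values of the eight-scanner
multi-centre volunteer study whose design the simulator replicates. The
underlying scans are not public, so these printed summaries are used as
*inputs* to the CV/ICC arithmetic (worked examples and regression tests),
never as things the package claims to re-derive from images. The
regression tests document, cell by cell, where the printed tables are
internally inconsistent: eleven CV cells differ by one unit in the last
printed digit (the source computed CVs from unrounded SDs), two printed
inter-scanner SDs are inconsistent with their own printed CV and mean by
exactly a dropped digit, and in eight rows — six of them in the ADC
sub-region block — the printed ICC does not equal the variance-ratio
arithmetic of the printed SDs (the white-matter ADC ICC, for instance,
prints 0.90 where the printed SDs give 0.8948). The tests pin the
verified agreement and assert the known discrepancies explicitly, so any
silent change to the bundled tables fails loudly.

## Problem sizes and determinism

The test suite simulates small volumes (phantom grids of 16–28 voxels per
side, one to three slices) and checks Monte-Carlo properties at 50–200
replicates; the variance-recovery check uses 200 replicates of an
8-scanner × 6-volunteer × 2-session balanced design. These sizes were
chosen so the full suite runs in well under a minute on one core while
leaving Monte-Carlo standard errors several times smaller than the
tolerances being asserted. End-to-end pipeline runs are byte-identical
for identical configuration and seed; manifests deliberately contain no
timestamps.

## Known limitations

* The segmented IVIM fit assumes the b-value set brackets both regimes;
  with no b-values below 300 s/mm² the perfusion fraction is
  unidentifiable and the voxel is flagged invalid.
* The tensor fit is unweighted log-linear; at very low SNR weighted or
  nonlinear estimators would be less biased.
* The simulators draw homoscedastic Gaussian/Rician noise; physiological
  noise, motion and cardiac pulsation are not modelled.
* `NE` reporting depends on the REML boundary behaviour of `lme4`; a
  different optimiser could flag a slightly different replicate subset.
* Real multi-centre tables with missing cells (scanner–volunteer pairs
  never scanned) are handled by the mixed model, but severely unbalanced
  designs will widen the uncertainty of $\sigma_{inter}$ in ways the
  point estimates do not convey.
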