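# dwirepro

Multi-centre reproducibility analysis of quantitative diffusion MRI
parameters.

When diffusion-weighted MRI data are pooled across scanners — as in
multi-centre clinical studies of rare diseases, where no single site can
recruit enough patients — the first question is whether a measured change
in a diffusion parameter reflects biology or merely the scanner it was
acquired on. `dwirepro` is an R package for answering that question. It is
aimed at imaging scientists and biostatisticians who need to (a) quantify
inter-scanner, inter-volunteer and intra-scanner variability of ADC, IVIM
and DTI parameters from test–retest study tables, and (b) validate the
whole estimation chain on simulated phantom and brain-like data with known
ground truth.

## What it computes

**Signal models.** The mono-exponential model `S(b) = s0·exp(−b·ADC)`
fitted log-linearly over the clinical b-values; the bi-exponential
intra-voxel incoherent motion (IVIM) model

    S(b) = s0 · ( f·exp(−b·D*) + (1 − f)·exp(−b·D) )

fitted in the segmented (stepwise-sequential) manner — D from the b ≥ 300
s/mm² log-linear fit, then f and D* by Nelder–Mead with D fixed, iterated
to remove the residual perfusion bias in D — and the diffusion tensor
fitted by log-linear least squares, with MD and FA from its eigenvalues.

**Reproducibility statistics.** A scanner-fixed / volunteer-random mixed
model fitted by REML (`lme4`) decomposes each metric in each region into a
grand mean μ and three standard deviations: σ_inter (SD of the estimated
scanner means), σ_volunteer (random-effect SD) and σ_intra (residual SD).
These become coefficients of variation `CV = 100·σ/μ` and the intraclass
correlation pair

    ICC_inter = σ_inter² / (σ_inter² + σ_intra²),   ICC_intra = 1 − ICC_inter .

For phantom data the simple group CV (`100·sd/mean` over per-scanner
means) with leave-one-scanner-out recomputation is provided, and the
mixed model can be run separately per field strength (1.5 T vs 3 T).

**Simulation with known truth.** An ice–water phantom generator (five
water tubes at the 0 °C reference diffusivity 1.099 × 10⁻³ mm²/s plus a
sucrose tube), a brain-like multi-centre study generator (8 scanners,
4–8 of 9 volunteers each, repeat sessions, 65 sessions in total) with
additive scanner fixed effects and volunteer random effects, and Rician
magnitude noise — the two-channel noise whose rectified floor biases FA
and the perfusion fraction upward at low SNR.

## Worked example

```r
library(dwirepro)

## simulate one noisy brain-like voxel and fit the segmented IVIM model
sc    <- dwiScheme()                      # b = 0, 50, 100, 300, 500, 600, 1000
truth <- ivimParams(s0 = 1000, d = 0.7e-3, dStar = 10e-3, f = 0.1)
sig   <- addRicianNoise(ivimSignal(truth, sc), sigma = 10, seed = 7)
fitIVIM(sig, sc)
#> IVIMFit: D = 0.000665393, f = 0.14094, D* = 0.01269 (sse = 250.884)
```

At SNR 100 the fit lands near the generating values (D within ~5%); the
apparent f of 0.14 against a true 0.1 is the familiar noise sensitivity of
the perfusion fraction.

```r
## group CV over the bundled published per-scanner phantom ADC means
ph <- phantomScannerMeans()
groupCV(ph$mean[ph$metric == "ADC"])
#> $mean 1.115  $sd 0.0167  $cv 1.493
```

A 1.5% CV across eight scanners: ice–water ADC is highly reproducible.

```r
## end-to-end: simulate the 65-session replica study and report CV/ICC
cfg <- runConfig("volunteer-study", seed = 11, params = list(bySubgroup = FALSE))
res <- runVolunteerPipeline(cfg)
head(formatReport(res$report), 4)
#>   metric region subgroup   mean cv_inter cv_volunteer cv_intra icc_inter icc_intra mdc
#> 1    ADC     GM      all 0.8191      3.5          3.6      2.7      0.64      0.36 7.0
#> 2    ADC     WM      all 0.6938      3.5          1.8      1.1      0.92      0.08 7.0
#> 3      D     GM      all 0.7353      2.1          2.6      2.3      0.46      0.54 4.2
#> 4      D     WM      all 0.6373      2.4          0.9      2.0      0.61      0.39 4.9
```

Each row gives, per metric and region, the model mean (diffusivities in
10⁻³ mm²/s), the three CVs in percent, the ICC split between scanner and
session variance, and the minimum detectable change (`2 × CV_inter`): a
white-matter ADC change smaller than ~7% here could be scanner effect
alone.

## Package layout

* `R/` — S4 classes (`AcquisitionScheme`, `IVIMParams`, `StudyDesign`,
  `VarianceComponents`, …), simulators, fitters, ROI tools, statistics,
  pipelines.
* `inst/extdata/` — published summary tables used as worked-example
  inputs (plain CSV).
* `inst/scripts/dwirepro.R` — thin command-line wrapper over the
  pipeline functions.
* `vignettes/dwi-reproducibility.Rmd` — the methods vignette: models,
  assumptions, numerical choices and limitations.
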