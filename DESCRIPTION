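Package: dwirepro
Title: Multi-Centre Reproducibility Analysis of Diffusion MRI Parameters
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the test-retest and multi-scanner
    reproducibility of quantitative diffusion MRI parameters. Provides
    forward simulation of diffusion-weighted signals from mono-exponential
    (ADC), bi-exponential intra-voxel incoherent motion (IVIM) and
    diffusion-tensor models with Rician magnitude noise; an ice-water
    phantom and multi-centre volunteer study simulator with known ground
    truth; voxelwise ADC, segmented-IVIM and log-linear tensor fitting;
    region-of-interest summarisation with probability-map thresholding and
    morphological erosion; and mixed-model variance-component
    reproducibility statistics (inter-/intra-scanner and inter-volunteer
    coefficients of variation and intraclass correlation coefficients),
    including field-strength subgroup analysis and end-to-end pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    lme4,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, MagneticResonanceImaging, Preprocessing, BatchEffect
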