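Package: ntramed
Title: Trimodal Radiodensity Modelling and Mediation Analysis of Muscle Aging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a trimodal skew-Gaussian model to mid-thigh computed
    tomography radiodensity histograms (Hounsfield units, -200 to 200),
    yielding eleven subject-specific parameters describing fat, loose
    connective tissue, and lean muscle distributions as a quantitative
    construct for sarcopenia. Implements a four-step multiple-mediator
    regression pipeline relating self-reported physical activity to
    lower-extremity function through these radiodensity parameters:
    covariate-adjusted total-effect models, Holm-Bonferroni mediator
    screening, outcome and attenuation models, and subject-resampling
    bootstrap confidence intervals for indirect and direct effects. A
    synthetic-data module generates voxel samples and longitudinal cohorts
    with planted mediation structure so every stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
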