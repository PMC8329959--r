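Package: texsurv
Title: Filtration-Histogram CT Texture Features and Cutoff-Based Survival Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies tumor heterogeneity on single-slice CT images with the
    filtration-histogram technique (Laplacian-of-Gaussian band-pass filtration
    at spatial scales of 2-6 mm followed by first-order histogram statistics:
    mean, SD, mean of positive pixels, entropy, skewness, kurtosis) and links
    the resulting features to overall survival through ROC-derived optimal
    cutoffs, Kaplan-Meier curves, log-rank tests and Cox proportional hazards
    models. Includes synthetic CT tumor phantoms and Weibull
    proportional-hazards cohort simulators with known ground truth, so the
    whole chain is testable end to end, plus intraclass-correlation
    reliability analysis with qualitative agreement bands.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    survival,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
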