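Package: erlf
Title: Volume-Assisted Estimation of Remnant Liver Function from
    Gd-EOB-DTPA MR Relaxometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates total and remnant liver function from hepatobiliary
    T1 relaxometry (reduction rate of the T1 relaxation time after
    gadoxetic acid) combined with liver and resection volumetry, on the
    scale of the indocyanine green plasma disappearance rate (ICG-PDR).
    Provides monoexponential ICG clearance fitting (PDR, R15), the
    established preoperative and postoperative dysfunction
    classifications, post-hepatectomy outcome criteria (including the
    50/50 rule), diagnostic evaluation (confusion matrices, sensitivity,
    specificity, predictive values, ROC-AUC, exact Mann-Whitney tests,
    and exhaustive reconstruction of confusion matrices from published
    rounded metrics), Kaplan-Meier and univariable Cox survival analysis
    stratified by estimated remnant function, segmentation-mask
    volumetry, and a seeded synthetic-cohort generator that emulates the
    statistical structure of a hepatectomy study population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
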