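Package: walnutnir
Title: Hyperspectral NIR Chemometrics for Fat and Fatty-Acid Screening in Walnut Kernels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end near-infrared hyperspectral imaging chemometrics
    pipeline for non-destructive screening of total fat and fatty-acid
    composition (SFA, MUFA, PUFA and individual acids) in intact walnut
    kernels. Provides ENVI-style cube input/output with two-point radiometric
    calibration, stepwise linear-discriminant pixel segmentation with
    per-kernel spectrum extraction, WinISI-style spectral pretreatments
    (SNV, detrend, MSC and gap-segment derivatives), Mahalanobis H/NH sample
    selection, modified partial least squares (MPLS) calibration with
    cross-validated factor selection and T-statistic outlier elimination,
    validation statistics (SEC, SECV, SEP, bias, percent-of-range errors),
    variety-level composition statistics with ANOVA and Tukey grouping, and
    a synthetic scene/chemistry generator for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
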