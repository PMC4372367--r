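Package: dscquant
Title: Quantitative Dynamic Susceptibility Contrast Perfusion MRI Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end quantitative analysis of dynamic susceptibility
    contrast (DSC) perfusion MRI: conversion of 4D bolus-tracking signal to
    contrast concentration, automatic arterial input function selection by
    Cmax/TTP/fMTT ranking, cerebral blood flow estimation by truncated
    singular value decomposition deconvolution, blood volume by the
    indicator-dilution integral ratio, parenchyma and vessel masking,
    white-matter internal-standard calibration, VOI-level relative
    perfusion ratios, and nonparametric group comparison (exact and
    asymptotic Mann-Whitney U and Wilcoxon signed-rank tests). Includes a
    digital perfusion phantom with known regional ground truth and a
    matched patient/control cohort simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
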