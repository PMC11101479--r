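Package: binoccomb
Title: Models of Binocular Combination for Neural and Psychophysical Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling how the two eyes' responses combine into a
    single binocular response, at the level of V1 firing rates and of
    psychophysical contrast sensitivity. Implements four combination rules --
    Minkowski summation, gated power-law amplification of the dominant
    channel, Schroedinger's magnitude-weighted nonlinear average, and the
    Bayesian maximum-likelihood (inverse-variance) weighted average --
    together with nonlinear least-squares estimation of their parameters,
    per-observation Minkowski-exponent root finding, classification of
    neurons into facilitatory/suppressive subtypes and of subjects by
    binocular-enhancement screening, a synthetic-data generator that emulates
    the statistical structure of binocular single-unit and contrast
    sensitivity datasets, and an end-to-end analysis pipeline with CSV/JSON
    input and output and a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    ggplot2,
    minpack.lm,
    rlang,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
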