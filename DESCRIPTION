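Package: inhibitr
Title: Latent-Variable Analysis of Inhibitory Control Task Batteries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, preprocessing and latent-variable analysis of
    multi-task inhibitory control batteries (antisaccade, Stroop,
    stop-signal, flanker, shape-matching, word-naming). Generates
    trial-level data from a known two-factor model, applies a four-step
    robust trimming protocol, computes reaction-time difference scores
    and inverse efficiency scores including race-model stop-signal
    reaction times, estimates split-half reliabilities and Spearman
    correlations, and fits null, one-factor and two-factor confirmatory
    factor models by maximum likelihood with chi-square, RMSEA, SRMR,
    CFI, NFI and AIC fit indices, nonparametric bias-corrected
    bootstrap, and Mardia multivariate-normality diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
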