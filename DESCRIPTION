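Package: painconn
Title: Oscillatory Power and Phase Connectivity Analysis for 2x2
    Within-Subject EEG Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for testing whether experimental factors
    in a 2x2 within-subject design (stimulus intensity crossed with cued
    expectation) modulate local oscillatory power or interregional phase
    connectivity in source-space EEG. Provides a multi-subject synthetic
    signal generator with ground-truth bookkeeping, Slepian multitaper band
    power and cross-spectral estimation, frequency-specific LCMV
    beamforming, the debiased weighted phase lag index, bivariate partial
    directed coherence with an information-flow asymmetry score,
    Bayes-factor repeated-measures ANOVA with g-priors, a rank-based
    Bayesian one-sample test, Bayesian comparison of power-based versus
    connectivity-based logistic models, and repeated-measures power
    analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
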