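Package: accubeta
Title: Evidence Accumulation Modelling and Beta-Band Electrophysiology
    Pipelines for Sequential Decision Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing expanded judgment (sequential sampling)
    decision tasks together with simultaneously recorded neural time series.
    Implements leaky/bonus evidence-accumulation models with maximum-likelihood
    fitting and BIC model selection, choice-commitment logistic regression,
    Bayesian normalization and Shannon-surprise regressors, a baseline-free
    multitaper band-power pipeline (continuous sliding-window estimation,
    log transform, high-pass filtering of power, epoching), per-timepoint
    regression and condition contrasts with cluster-based permutation
    correction, and time-resolved coherence plus the debiased weighted
    phase-lag index. A synthetic-data module generates behaviour and
    two-channel oscillatory recordings with known ground truth so that every
    stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
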