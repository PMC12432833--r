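Package: fcoinirs
Title: Functional Channel-of-Interest Analysis for Block-Design fNIRS
Version: 0.1.0
Authors@R:
    person("fcoinirs", "developers", email = "fcoinirs@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing block-design functional near-infrared
    spectroscopy (fNIRS) experiments with an individual functional
    channel-of-interest (fCOI) approach. Provides a full preprocessing chain
    (channel pruning, optical-density conversion, linear detrending, temporal
    derivative distribution repair, zero-phase Butterworth band-pass filtering,
    modified Beer-Lambert inversion, PCA-based global-signal spatial
    filtering), windowed block-response extraction with run/participant
    exclusion rules, leave-one-run-out fCOI selection within anatomical search
    spaces, cross-task specificity estimation, linear mixed-effects group
    inference with Bonferroni family-wise control, a fully seeded synthetic
    cohort generator with known ground truth for validation, and construction
    of acoustically degraded speech control stimuli.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
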