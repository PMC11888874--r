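Package: cpetwave
Title: Wavelet and Support Vector Machine Analysis of Cardiopulmonary
    Exercise Testing Signals
Version: 0.1.0
Authors@R:
    person("cpetwave", "developers", email = "cpetwave@example.org",
           role = c("aut", "cre"))
Description: Tools to support diagnostic classification from breath-by-breath
    cardiopulmonary exercise testing (CPET) recordings.  Per-subject
    multichannel signals (heart rate, gas exchange, ventilation) are
    summarised by the means and variances of multilevel Daubechies
    discrete-wavelet-transform coefficients, and subjects are classified as
    heart failure, metabolic syndrome or healthy with soft-margin kernel
    support vector machines, either binary or combined pairwise through a
    one-vs-one error-correcting output code.  Includes repeated unstratified
    k-fold cross-validation with per-label confusion-matrix reduction, a
    seeded synthetic cohort generator with a rest/ramp/recovery phase
    structure for end-to-end testing, CSV readers for the two source data
    dialects, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
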