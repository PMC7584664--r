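Package: enstime
Title: Ensemble Averaging of Time Intervals: Simulation, Adaptive
    Psychophysics, and Model Comparison
Version: 0.1.0
Authors@R:
    person("Ensemble", "Timing Contributors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools for studying how observers average sets of time
    intervals. Implements four candidate ensemble-averaging schemes
    (arithmetic, geometric, weighted, harmonic) with scalar timing noise
    and additive bias; a synthetic-observer simulator that generates
    complete two-phase comparison sessions; an updated-maximum-likelihood
    (UML) adaptive procedure with a grid posterior over threshold, slope
    and lapse of a logistic psychometric function; offline maximum-
    likelihood psychometric fitting with PSE/JND extraction and AIC model
    comparison; and a difference-plane analysis that classifies observers
    as arithmetic- or geometric-oriented and fits the averaging models to
    observed points of subjective equality.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
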