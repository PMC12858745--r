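Package: earnoise
Title: Ear-Piece Noise Dosimetry and Hearing-Outcome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying occupational noise exposure from monaural radio
    ear-pieces and its association with hearing outcomes. Implements an
    energy-equivalent noise-dosimetry engine (career-long exposure energy,
    weekly-averaged exposure level, energy-weighted average volume-control
    setting), derivation of registered survey analysis variables (temporary
    threshold shift measures, tinnitus laterality, between-ear speech-in-noise
    difference scores), the registered descriptive and regression analyses
    (ordinal, logistic, ear-wise paired logistic, and linear models with an
    explicit covariate-screening rule and Sison-Glaz simultaneous multinomial
    confidence intervals), a two-down one-up adaptive digits-in-noise staircase
    simulator, and a synthetic-cohort generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    sandwich,
    survival,
    jsonlite,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
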