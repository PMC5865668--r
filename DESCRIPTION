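Package: rppaflow
Title: Reverse-Phase Protein Array Quantification and Downstream Analysis
Version: 0.1.0
Authors@R:
    person("PKG", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, end-to-end re-implementation of the quantitative
    analysis chain used in proteomic profiling studies of non-small cell
    lung cancer: dilution-series ("SuperCurve"-style) quantification of
    reverse-phase protein array slides, loading adjustment and median
    centering, two-group differential protein expression with
    beta-uniform-mixture false-discovery-rate control, cross-cohort
    concordance classification, Chou-Talalay interaction-index scoring of
    drug combinations, and generalized-least-squares modelling of
    longitudinal tumor growth with AIC correlation-structure selection and
    Tukey HSD contrasts. A synthetic-data generator with known ground
    truth drives every stage so the whole pipeline is testable without any
    external download.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite
Config/testthat/edition: 3
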