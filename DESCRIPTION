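Package: lymphtraffic
Title: Steady-State Markov Modelling of Lymphocyte Differentiation and
    Blood-CSF Trafficking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Four-stage Markov steady-state model of lymphocyte
    differentiation and transmigration between peripheral blood (PB) and
    cerebrospinal fluid (CSF).  Provides closed-form stationary stage
    distributions and per-compartment immune profiles, constrained
    least-squares calibration of transition rates from cohort
    flow-cytometry summaries together with structural-identifiability
    diagnostics, prediction of a patient's CSF naive/differentiated
    profile from blood measurements alone with bootstrap ranges, an
    event-driven stochastic simulation oracle whose stationary occupancy
    reproduces the model, a synthetic-cohort generator with binomial
    event-count noise, and CSV input/output with a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
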