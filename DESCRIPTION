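Package: eqsens
Title: Steady-State and Sensitivity Computation Methods for ODE Models of
    Biochemical Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes parameter-dependent steady states of ordinary
    differential equation models of biochemical reaction networks by
    numerical integration with a weighted root-mean-square stopping rule or
    by damped Newton iteration, and objective-function gradients at steady
    state by forward or adjoint sensitivity analysis, either integrated or
    tailored to the steady-state case as a single linear solve against the
    (transposed) Jacobian.  Supports pre- and post-equilibration
    likelihoods with steady-state measurements, automatic detection and
    removal of conserved quantities, structured failure classification, and
    a benchmark harness comparing the six admissible method pairs on
    built-in fixture models with closed-form steady states.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
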