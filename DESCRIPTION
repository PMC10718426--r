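Package: tugofwar
Title: Spatial-Exclusion Competition Dynamics in One-Dimensional
    Microchannels
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the competition of two cell species confined to a
    one-dimensional open microchannel, where dividing cells push their
    neighbours toward the channel ends and death occurs only by expulsion.
    Provides exact first-passage solvers (fixation probabilities,
    unconditional and conditional mean first-passage times) for arbitrary
    birth-death chains with absorbing ends, the Fokker-Planck continuum
    approximation with its effective potential, the deterministic
    fixation time and the asymptotic logarithmic decomposition of the
    maximal fixation time, a two-boundary invasion model solved exactly
    on its two-dimensional state space, and an event-driven cell-level
    stochastic simulator. The classical Moran model is implemented
    throughout as the well-mixed baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
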