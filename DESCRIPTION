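Package: wmcircuit
Title: Working Memory Circuit Models with Hybrid Positive and
    Negative-Derivative Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Firing-rate simulators for circuit-level models of working
    memory. Provides single-unit feedback memory models (positive feedback,
    negative-derivative feedback, and the hybrid of both), an
    excitatory/inhibitory mean-field population model with Naka-Rushton
    steady-state transfer, a redundant multi-unit storage network with
    stability and perturbation protocols, and a storage distribution
    network that routes, stores, refreshes, and forgets up to four memory
    items by winner-take-all selection and first-in-first-out eviction.
    Includes stimulus-schedule generators and recall readouts for
    trend-level replication of classic delayed-response, association,
    updating, feature-binding, and serial-position experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
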