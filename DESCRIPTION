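Package: openwalk
Title: Quantum-Markov Open-System Models of Choice and Confidence Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for modelling the dynamics of choice, confidence and
    preference on a discrete evidence lattice. Implements continuous-time
    Markov random walks, quantum walks, and their combination through a
    Lindblad (GKSL) master equation whose dissipator is weighted against the
    Hamiltonian term by a mixing weight w. Provides sequential projective
    measurement with the Lueders rule, superoperator (vectorised) and ODE
    propagation of density matrices, stationary-state solvers, interference
    (Chapman-Kolmogorov violation) statistics, synthetic choice-confidence
    experiments, and maximum-likelihood recovery of the mixing weight.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    rlang,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
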