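Package: relkin
Title: Mechanism-Decomposed Modelling of Drug Release Kinetics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits cumulative drug-release profiles with a composite model that
    decomposes release into burst, Fickian plane-sheet diffusion and osmotic
    pumping contributions, with simplex-constrained mechanism weights. The
    constrained least-squares fit is solved by a sequential quadratic
    programming (SQP) engine with active-set quadratic subproblems, damped
    BFGS Hessian updates, an l1-merit line search and KKT-based convergence.
    Includes porous-membrane hydraulics (Poiseuille pressure drop, hydraulic
    permeability, reflection coefficient), correlation models linking kinetic
    constants to drug load and flow rate for predicting unseen conditions, a
    synthetic release-profile generator, CSV/JSON input and output, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
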