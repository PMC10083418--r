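Package: fhnnet
Title: FitzHugh-Nagumo Dynamics on Multilayer Cartesian-Product Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Analysis and simulation of the FitzHugh-Nagumo neural model
    coupled through a multilayer (Cartesian-product) network. Provides
    equilibrium solution and classification via the cubic discriminant,
    local stability tests, network Turing-instability criteria driven by
    the Kronecker-sum Laplacian spectrum, delay-induced Hopf bifurcation
    thresholds from the transcendental characteristic equation,
    center-manifold normal-form coefficients (first Lyapunov quantity,
    bifurcation direction, Floquet exponent, period correction), and
    fixed-step deterministic, delayed and stochastic integrators for
    pattern and synchrony studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
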