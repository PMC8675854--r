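Package: bgctdyn
Title: Bifurcation and Potential-Landscape Analysis of a
    Cortex-Basal Ganglia-Thalamus Firing-Rate Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing a seven-population firing-rate model of
    the cortex-basal ganglia-thalamus loop under low dopamine. Provides
    the vector field with its exact Jacobian, multistart equilibrium
    enumeration with linear stability classification, codimension-one
    pseudo-arclength continuation with fold and Hopf detection,
    codimension-two fold/Hopf curve tracing with cusp points and regime
    maps, simulation-based attractor censuses (stable steady states and
    limit cycles with period and beta-band classification), and potential
    landscapes U = -ln(Pss) estimated from ensembles of Langevin
    simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
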