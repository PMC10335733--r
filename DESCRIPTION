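Package: t6sim
Title: Agent-Based Simulation of Type VI Secretion System Competition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic modelling of contact-dependent bacterial warfare with
    the type VI secretion system (T6SS). Implements a two-stage subcellular
    kinetic model (delayed activation followed by an immigration-death process
    of sheath assembly and firing), with closed forms, exact stochastic
    simulation, master-equation integration, curve fitting and count-histogram
    statistics. The kinetic model is embedded in a two-dimensional off-lattice
    agent-based model of spherocylindrical cells growing in a monolayer (adder
    division, overdamped contact mechanics, clonemate-immune contact killing
    with delayed lysis), together with scenario runners for in-silico
    coincubation experiments: unprimed and primed duels, lethal versus unarmed
    target elimination, range expansion, and cost-lethality phase sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
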