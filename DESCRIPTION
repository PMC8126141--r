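Package: ptlkin
Title: Kinetic Modeling of Cellular Exposure to Plasma-Treated Liquid
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-compartment mass-action kinetic model of a cell exposed to
    plasma-treated liquid (hydrogen peroxide plus nitrite). Simulates the
    stiff coupled rate equations of the catalase-H2O2-peroxynitrite redox
    network with first-order membrane diffusion between the extracellular
    and intracellular compartments, initializes intracellular H2O2 at its
    kinetic steady state, and computes susceptibility measures (temporal
    maxima, response time, loads, consumption rates) from the trajectories.
    Provides parameter sweeps over the H2O2 membrane diffusion rate constant
    and the intracellular catalase concentration, with selectivity and
    synergy summary ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
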