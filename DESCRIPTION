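Package: crosstalksim
Title: Kinetic Simulation of Signaling Crosstalk Modules and In Silico Drug Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Michaelis-Menten kinetic models of two growth-factor-driven
    signaling cascades coupled by crosstalk links, simulated with a fixed-step
    fourth-order Runge-Kutta integrator. Provides a registry of nine canonical
    crosstalk module topologies, targeted-drug perturbation of activation
    kinetics, relative drug efficacy scoring against the crosstalk-free
    baseline module, Bliss-independence combination-index scoring of drug
    pairs, and screening drivers for single-drug efficacy, pairwise drug
    combinations, crosstalk-strength scans and stimulus-variation scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    ggplot2,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
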