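Package: capnet
Title: Phase-Ternary Action Potential Simulation on Neurite Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discrete-event simulation of computational action potentials
    (CAPs) as phase-ternary pulses travelling on directed neurite graphs.
    A pulse carries a threshold front (+1), an analog refractory tail (-1)
    and a soliton energy budget that dissipates linearly with distance;
    pulses annihilate on head-on collision, merge when they arrive in phase
    at a junction, are annulled when they arrive inside the refractory
    window left by an earlier pulse, and fail to propagate when residual
    energy falls below the activation threshold. Includes synthetic network
    generators (parallel ladders, chains, binary trees, two-entry collision
    edges), SWC morphology import, a native JSON graph format, a
    time-stepped verification oracle, noise-redaction experiments on
    parallel ladders, and physical feasibility calculators (charge-diffusion
    speed limit, temporal accuracy, Moens-Korteweg pulse-wave velocity).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
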