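Package: adsim
Title: Inflammation-Driven Simulation of Amyloid-Beta and Tau Dynamics in
    Alzheimer's Disease
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the joint dynamics of intraneural and extraneural
    amyloid-beta, hyperphosphorylated tau, neurofibrillary tangles,
    microglia, astrocytes and neurons under time-ramped, spatially
    heterogeneous inflammation drivers. The reaction network can be solved
    as a well-mixed ODE system or as a two-dimensional reaction-diffusion
    system with flux-limited microglial chemotaxis and no-flux boundaries,
    on rectangular or masked grids. Includes seeded generation of
    pixel-class inflammation maps, calibration of production rates to a
    healthy-tissue fixed point, a drug-treatment extension that slows
    amyloid and tau accumulation, and threshold-crossing analytics on a
    PET-scan sampling cadence for in-silico longitudinal study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
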