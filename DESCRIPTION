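Package: ciliaflux
Title: Flux-Balance Modeling of Kinesin-II Recycling and Ciliary Length Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Deterministic flux-balance model of intraflagellar transport (IFT)
    in which a conserved pool of kinesin-II motors carries material to the
    ciliary tip and returns by diffusion. Provides the length-dependent IFT
    injection rate, motor-pool partitioning into ballistic, diffusive and basal
    fractions, three assembly/disassembly rate laws (motor-limited,
    tubulin-limited, length-dependent disassembly) with closed-form steady
    states, adaptive ODE simulation of ciliary regeneration, speed-to-length
    scaling curves, phase-space sweeps over motor number and diffusion
    constant, synthetic regeneration and injection-rate datasets, and
    least-squares parameter recovery from simulated time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
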