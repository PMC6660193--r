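Package: poreblock
Title: Kinetics, Ion Titration and Unbinding Energetics of Peptide-Toxin
    Pore Block
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis of pore-blocking peptide toxin kinetics in
    voltage-gated potassium channels from two-electrode voltage-clamp
    data.  Converts wash-in/wash-out time courses and paired control/toxin
    current traces into association and dissociation rate constants and
    their voltage dependence; fits Langmuir isotherms describing how the
    rate constants depend on external potassium; fits a four-state
    closed/open blocked/unblocked equilibrium model with Boltzmann gating
    and microscopic reversibility to tonic-inhibition data; decomposes
    dissociation rates into Eyring activation energies and per-contact
    equilibria; and simulates a stochastic contact-network ("wobbling")
    model of multi-contact unbinding.  Includes seeded synthetic-data
    generators emulating oocyte recordings so every stage is testable
    without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
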