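Package: phfeedback
Title: pH-Mediated Microbial Interactions: Simulation, Phase Diagrams and
    Motif Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models how bacteria modify the pH of their environment and react
    to that modification. Couples logistic population growth with a Gaussian
    pH niche to an environmentally bounded proton-concentration dynamic,
    integrates the system over continuous batches and periodic
    serial-transfer (growth-dilution) protocols, sweeps initial conditions
    into survival phase diagrams, and classifies pairwise interaction motifs
    (bistability, successive growth, extended suicide, stabilization). Also
    provides a discrete-time Mamdani fuzzy-logic counterpart of the dynamics,
    linear stability analysis of fixed points, estimation of species pH
    niches and pH drives from growth-assay tables, and a synthetic-data
    generator emulating colony-count plating noise and pH-meter noise for
    end-to-end recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
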