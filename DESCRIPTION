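Package: periphos
Title: Periplasmic Phosphate Accumulation Kinetics in Marine Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative framework for studying how marine picocyanobacteria and
    heterotrophic bacteria accumulate inorganic phosphate (Pi) in the periplasm.
    Implements diffusion-theory clearance-rate ceilings (Berg-Purcell sphere and
    porin-patch absorbers), a dual-isotope pulse-chase compartment model of
    seawater -> periplasmic buffer -> cytoplasmic labile -> macromolecule pools with
    treatment-specific measurement operators (seawater wash, hypotonic wash, PFA and
    TCA fixation), metabolic-inhibitor event scheduling, isotope-dilution
    concentration-series bioassay inference, tracer-depletion clearance estimation,
    micro-beam synchrotron X-ray fluorescence quota calibration, and periplasm
    capacity/osmolarity feasibility arithmetic. Ships a synthetic-data generator with
    Poisson counting noise so every estimator can be exercised end-to-end, and a
    least-squares fitter with bootstrap intervals for pulse-chase time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    yaml
Config/testthat/edition: 3
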