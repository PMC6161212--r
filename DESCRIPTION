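Package: meltrheo
Title: Model-Based Melt Viscosity for Hot-Melt Extrusion of Amorphous
    Solid Dispersions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the melt-viscosity flow curve of a drug/polymer
    amorphous solid dispersion from its glass-transition temperature (Tg)
    and the rheological characterisation of the pure polymer matrix.
    Implements Couchman-Karasz and BCKV glass-transition mixing models,
    API-in-polymer solubility phase diagrams from annealing DSC records,
    time-temperature superposition master curves with WLF shift factors,
    Carreau-Yasuda flow-curve fitting, an exponential Tg to zero-shear
    viscosity correlation, specific mechanical energy of twin-screw
    extrusion, and a simplified one-dimensional viscous-dissipation
    energy demonstrator, together with synthetic-data generators with
    known ground truth for every fitting stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
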