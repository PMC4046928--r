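Package: tractionfem
Title: Finite-Element Traction Force Microscopy for Multi-Cellular Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Recovers the traction forces that adherent cells and cell
    clusters exert on soft elastic substrates of finite thickness.  A
    structured hexahedral linear-elastic finite-element model of the gel
    slab is solved as a mixed boundary value problem: measured surface
    displacements are prescribed under the cells, zero traction outside
    them, and the nodal reactions give the traction field directly,
    without regularization or a half-space (Boussinesq) assumption.  An
    iterative whole-field displacement variant, a forward simulator for
    validation by round trip, a basic digital image correlation routine
    for bead images, and mesh-convergence / Poisson-ratio / region-choice
    study drivers are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    tiff,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
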