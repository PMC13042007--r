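Package: fracturelattice
Title: Mechanics of the Honeycomb Fracture Lattice in Spiny Mouse Skin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models the mechanics of skin built as a honeycomb composite of
    stiff collagen walls surrounding compliant lipid-filled cells, the
    architecture that lets spiny mouse (Acomys) skin tear along predetermined
    boundaries (skin autotomy). Provides construction of the hexagonal
    lattice geometry and its boundary-segment inventory, rasterised
    collagen/lipid material maps with cut or ripped wound defects, linear
    plane-stress finite-element analysis and a heterogeneous thin-plate
    bending solver with von Mises post-processing, line profiles,
    stress-concentration ratios and mesh-convergence checks, a quasi-static
    cohesive-zone spring-lattice fracture simulator for pinch, opening and
    tearing loadings, and analysis of sawtooth force-displacement records:
    peak and interval extraction, decomposition of tearing increments into
    integer combinations of long and short boundary lengths, a Monte-Carlo
    discreteness test, and worm-like-chain curve fitting. Seeded synthetic
    generators produce every input the pipeline needs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
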