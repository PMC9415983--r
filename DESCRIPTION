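Package: siskoflow
Title: Sisko Nanofluid Boundary-Layer Flow in Porous Stenosed Arteries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator for steady boundary-layer flow and heat transfer of a
    gold-nanoparticle/blood Sisko nanofluid along a porous, cosine-stenosed
    artery. Provides Brinkman/Maxwell effective-property correlations, the
    similarity-reduced coupled momentum/energy ODE system with curvature,
    Darcy porous-drag and viscous-dissipation terms, a shooting solver for the
    two-point boundary value problem with an independent spectral-collocation
    cross-check, wall skin-friction and Nusselt groups, reconstruction of
    dimensional velocity and temperature fields in the stenosed geometry, and
    a parameter-sweep engine with comparison-table reproduction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
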