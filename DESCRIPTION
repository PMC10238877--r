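Package: carotidtwin
Title: Digital-Twin Hemodynamics of the Stenosed Carotid Bifurcation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds parametric digital twins of the carotid bifurcation with
    graded NASCET stenoses, meshes them with diameter-adaptive tetrahedral
    grids, and solves blood flow with a Poiseuille inlet profile, two-element
    Windkessel outlets and an area-based outlet resistance split. Two solver
    engines are provided: a reduced-order vessel network with quadratic
    stenosis pressure-drop elements and a three-dimensional incompressible
    Navier-Stokes finite-element engine. Readouts include internal carotid
    peak systolic velocity from a virtual probe, trans-stenotic pressure
    drop under simulated hyperemia, quadratic pressure-drop/flow fits and an
    FFR-like pressure ratio. A validation toolkit implements Doppler
    ultrasound versus computed velocity agreement analysis (probe-offset
    adjustment, Bland-Altman limits of agreement, ICC(2,1), regression,
    subgroup tables, margin coverage and ICC-based sample-size planning)
    together with a seeded synthetic cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
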