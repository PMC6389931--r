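Package: mosaicbif
Title: Bifurcation Analysis of a Forest-Grassland Mosaic Model with
    Human Feedback
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Codimension-1 and codimension-2 bifurcation analysis of a
    planar forest-grassland mosaic ecosystem model coupled to human
    opinion dynamics.  Provides analytic derivative tensors up to third
    order, pseudo-arclength continuation of equilibria, Andronov-Hopf
    detection with first Lyapunov coefficients, Bautin (generalized
    Hopf) point location, limit-cycle continuation through a Poincare
    return map with Floquet multipliers and fold-of-cycles (LPC)
    detection, two-parameter regime maps in the plane spanned by the
    fire-activation steepness and the natural forest-conversion rate,
    and simulation utilities for catastrophic versus smooth
    regime-shift experiments.  Hopf and Bautin normal-form benchmark
    systems with closed-form bifurcation structure are included for
    validation of every numerical stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
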