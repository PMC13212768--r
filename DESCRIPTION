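Package: stenowss
Title: Synthetic Stenotic Coronary Geometry and Graph-Based Wall Shear Stress Surrogates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates cohorts of synthetic stenotic coronary artery
    geometries (parametric centerlines, four lesion morphology classes,
    structured wall lattices with STL/VTP/CSV export), produces physically
    plausible wall shear stress (WSS) fields with a reduced-order
    quasi-one-dimensional hemodynamic oracle, encodes the vessel wall as a
    feature tensor and hybrid grid/spatial graph, and trains and benchmarks
    three surrogate regressors implemented from first principles: a
    dual-autoencoder multilayer perceptron, a U-Net, and a physics-informed
    graph neural network whose loss couples data misfit with gradient,
    continuity and inlet-boundary constraints. Includes Bland-Altman
    agreement analysis, axial WSS profiles and unwrapped-surface reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    grDevices,
    graphics,
    rlang,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
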