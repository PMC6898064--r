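Package: valvecae
Title: Surrogate Deep Learning of Bioprosthetic Aortic Valve Closure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts closure deformations and coaptation area of tri-leaflet
    bioprosthetic aortic valves directly from their NURBS control-point
    geometry, transvalvular pressure, and leaflet material properties.
    Provides a NURBS evaluation kernel (basis functions, derivatives, area
    quadrature, control-grid texture representation), a parametric valve
    designer, a fast synthetic closure simulator with known ground truth, a
    convolutional autoencoder trained with a boundary-condition-weighted
    loss, shape-comparison metrics (Euclidean, Hausdorff, Procrustes),
    Green-Lagrange strain fields, and an end-to-end pipeline with parameter
    sweeps and t-SNE embedding of the learned code layer.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lhs,
    pracma,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    vegan,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
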