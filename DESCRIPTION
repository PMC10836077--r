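Package: vasctrees
Title: Labeled Vascular Trees from Image-Derived Centerlines with 1D
    Hemodynamics and Geometric Uncertainty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Turns noisy vessel centerlines extracted from medical images
    (ordered 3D point sequences carrying maximally-inscribed-sphere radii
    plus parent/daughter connectivity) into labeled directed trees with
    uncertainty-annotated vessel dimensions. Provides junction relocation
    into the ostium, change-point detection (binary segmentation with a BIC
    penalty) and broken-line regression for radius extraction, network
    pruning and consistency checks, asymmetric self-similar structured
    trees with a diameter-dependent blood viscosity law, a two-step
    Lax-Wendroff solver for the nonlinear 1D blood flow equations with
    structured-tree impedance outflow boundary conditions, and Monte Carlo
    propagation of radius uncertainty to pressure and flow predictions.
    Readers and writers for VTK XML polydata, CSV centerline tables and a
    JSON tree format are included, along with seeded synthetic-centerline
    generators used as ground-truth fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
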