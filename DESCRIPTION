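Package: stenofem
Title: Stabilized Finite Elements for Magnetohydrodynamic Power-Law Blood
    Flow in Stenosed Bifurcated Arteries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Steady, two-dimensional, incompressible generalized power-law
    flow with a transverse magnetohydrodynamic body force, solved by a
    Galerkin Least-Squares stabilized equal-order (P1/P1) finite element
    method on a parametric bifurcated-artery domain containing an
    overlapping stenosis.  Provides closed-form wall geometry, mapped
    triangular meshing with stenotic refinement, a Newton-Raphson solver
    with Stokes initialization and parameter continuation, and hemodynamic
    post-processing: wall shear stress, wall pressure, cross-section
    velocity profiles, streamfunction, and recirculation-zone metrics.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
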