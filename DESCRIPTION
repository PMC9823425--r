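Package: csifem
Title: Contrast Source Inversion Microwave Imaging with Edge-Element FEM
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative microwave imaging by the contrast source inversion
    (CSI) method coupled to a curl-conforming finite-element solver on
    tetrahedral meshes.  Implements the discretized vector wave equation with
    lowest-order edge (Whitney/Nedelec) elements, a first-order absorbing
    boundary condition, TEM coaxial-port and elementary-dipole acquisition
    models, and two discretizations of the contrast source variable: the
    classical per-cell vector coefficients and an edge-basis scalar-coefficient
    representation that shares the field basis and is exactly consistent with
    the discretized wave equation.  Includes a synthetic layered head-phantom
    generator with a blood-like stroke inclusion, residual and cost-functional
    accuracy diagnostics, stroke-region statistics, and command-line entry
    points for simulation and inversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
LinkingTo:
    Rcpp
Config/testthat/edition: 3
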