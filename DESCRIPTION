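Package: tmsbem
Title: Charge-Based Boundary Element Modeling of TMS-Induced Electric Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasistatic modeling of the electric field induced in nested
    volume-conductor head models by transcranial magnetic stimulation (TMS)
    coils. Surfaces carry an induced charge density governed by a Fredholm
    integral equation of the second kind, discretized by centroid collocation
    on triangulated conductivity interfaces with analytic near-field triangle
    integrals. The system is solved either iteratively (unrestarted GMRES,
    matrix-free or dense) or by a reusable dense LU factorization so that many
    coil placements share one decomposition. Includes STL input/output,
    synthetic multilayer-sphere head models and figure-8 coils, analytic
    sphere oracles, relative vector-field error metrics, and an end-to-end
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
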