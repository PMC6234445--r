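Package: bronchoflow
Title: Steady Laminar Airflow in Age-Specific Tracheobronchial Airway Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Construction of symmetric in-plane bifurcating tracheobronchial
    airway models (generations G6-G9) for infant, child and adult from
    tabulated morphometric dimensions; derivation of age-specific respiratory
    flow parameters (minute ventilation, phase flow rates, Reynolds and
    Womersley numbers); Cartesian-core volume meshing with a grid-convergence
    mesh-independence procedure; a deterministic staggered finite-volume
    SIMPLE solver for steady incompressible laminar flow; and post-processing
    of velocity, pressure drop, wall shear stress and streamlines, with an
    orchestrated multi-age, two-phase study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
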