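Package: vcellsim
Title: Cell-Centered Agent-Based Simulation on a Dynamic Delaunay/Voronoi Grid
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An off-lattice, cell-centered agent-based simulation framework.
    Agents own generator points in 2D or 3D continuous space; their spatial
    extents are the Voronoi cells (V-cells) induced by a dynamic Delaunay
    triangulation that is rebuilt as agents act. Provides a robust
    Bowyer-Watson triangulation kernel (2D and 3D), Voronoi cell extraction
    with exact 1-hop neighborhoods, biomimetic agent behaviors (movement,
    growth, division, removal, absorption, rigid rotation), a seeded
    discrete-step engine with JSON checkpointing, scenario CSV and YAML
    configuration readers, legacy ASCII VTK export, and fixture generators
    for cyst layouts and random point clouds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
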