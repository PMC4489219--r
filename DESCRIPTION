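Package: vorocav
Title: Molecular Voids and Channels from the Voronoi Diagram of Atoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Recognizes internal voids and through-channels in molecular
    structures using the additively weighted Voronoi diagram of spherical
    atoms, its quasi-triangulation dual and the beta-complex. For a probe
    radius the package trims the Voronoi structure against the Lee-Richards
    (solvent accessible) offset model, classifies the connected components of
    the complement into the exterior space and voids, extracts channel spines,
    openings, topological handles and bottlenecks from the Voronoi graph, and
    measures van der Waals and cavity volumes and boundary areas. Includes a
    plain-text quasi-triangulation cache format, synthetic fixture generators
    with closed-form geometry, a PDB reader with a van der Waals radius table,
    and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
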