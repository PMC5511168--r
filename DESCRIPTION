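Package: capsidr
Title: Caspar-Klug Lattice Geometry and Spiral Assembly Simulation for
    Giant Icosahedral Virus Capsids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the lattice geometry of large icosahedral virus
    capsids. Computes Caspar-Klug triangulation numbers from (h,k) lattice
    indices, enumerates capsomer sites on the twenty icosahedral faces,
    partitions a capsid into twelve pentasymmetrons and twenty
    trisymmetrons with per-capsomer orientation classes, simulates the
    spiral assembly pathway that nucleates at a five-fold vertex, folds
    the flat lattice net onto a three-dimensional icosahedron with
    physical-scale calibration, exports pseudo-atom models (PDB, OBJ,
    CSV), and recovers (h,k) from tables of capsomer-center coordinates,
    including a synthetic center generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
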