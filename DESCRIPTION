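Package: latticectx
Title: Context-Aware Lattice Mapping and Subtomogram Averaging for Pleomorphic Capsids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating and averaging hexamer/pentamer lattices of
    pleomorphic retroviral capsid-like particles in cryo-electron tomograms.
    Provides synthetic lattice generators (tubes, T=1/T=3 icosahedra, closed
    polyhedra) rendered into noisy missing-wedge density volumes, constrained
    cross-correlation template matching, connectivity-network filtering,
    context-based classification of unit pairs into six groups, correlation-weighted
    consensus alignment of positions and normal vectors, class-geometry
    optimization, symmetry-aware wedge-weighted averaging with Fourier shell
    correlation resolution estimation, and interface RMSD analysis of atomic models.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    bio3d,
    yaml,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
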