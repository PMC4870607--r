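Package: poreperc
Title: Transport Pathway Analysis of Porous Scaffolds by Sphere
    Accessibility and Percolation Scaling
Version: 0.1.0
Authors@R:
    person("poreperc", "developers", email = "poreperc@example.org",
           role = c("aut", "cre"))
Description: Parameterizes the transport pathways through 3D binary
    images of porous materials such as freeze-dried tissue-engineering
    scaffolds. Given a voxelized pore/wall volume with isotropic spacing,
    the package measures the largest connected pore fraction (flood
    fill), the pore space accessible to a virtual sphere of any diameter
    entering from all surfaces or from a single face (distance-transform
    "shrink-wrap" accessibility), percent interconnectivity as a function
    of sphere diameter, and the percolation diameter d_c: the largest
    sphere that can travel infinitely far through the structure in a
    given direction, obtained by extrapolating maximum accessible
    distance against diameter with the 3D percolation correlation-length
    exponent. Includes synthetic phantom generators (throat lattices,
    lamellar and equiaxed foam structures) with known ground truth, an
    exact brute-force accessibility oracle, multipage TIFF / raw volume
    I/O, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
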