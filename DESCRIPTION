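Package: canonshape
Title: Canonical Parameterizations and Section Distances for Planar Contours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Shape analysis of closed planar contours via canonical
    parameterizations. Normalizes contours over the finite-dimensional
    shape-preserving groups (travel direction, starting point, scale,
    position, rotation), mods out the infinite-dimensional
    reparameterization group with a two-parameter family of
    curvature-weighted clock parameterizations, and measures shape
    dissimilarity with a section-based L2 distance. Includes Dunn and
    Davies-Bouldin cluster-validity indices, grid-search metric learning
    over the section parameters with a distance-matrix k-nearest-neighbour
    harness, an orientation-bias diagnostic, a seeded generator of labeled
    leaf-like synthetic contours, contour readers/writers and binary-mask
    boundary extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
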