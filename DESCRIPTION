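Package: tomoaccess
Title: Probe-Size-Resolved Accessibility Analysis of Segmented Tomograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how much of a porous material's internal surface a
    spherical probe of a given radius can reach, starting from 3D binary or
    labelled segmentations such as electron tomograms of plant cell walls.
    Implements the exact Euclidean distance transform, the covering radius
    transform (local thickness) by maximal-sphere painting, a join tree
    (contour tree) of the distance field with an accessibility-tagging
    algorithm that yields seed-dependent accessible distance and covering
    radius transforms, marching-cubes surface extraction with a
    range-of-interaction accessibility sampling, and accessible-surface-area
    versus probe-radius curves. Ships synthetic phantom generators with
    analytically known pore structure, independent widest-path oracles, and
    readers/writers for MRC, NRRD and TIFF volumes, PLY/OBJ/VTK meshes and
    CSV curves.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
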