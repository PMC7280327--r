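Package: muscledecomp
Title: Muscle Fibre Decomposition and Moment-Arm Analysis from Surface Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes a segmented skeletal-muscle surface mesh into an
    arbitrary number of polyline fibres using a harmonic scalar field between
    the attachment areas, isoline contour extraction, and generalized
    (mean-value) barycentric mapping of a fibre-architecture template.
    Animates the fibres across ball-and-socket joint poses with two-bone
    blended rigid transforms and computes per-fibre moment arms by the
    tendon-excursion method, alongside a minimal straight-lines (via point)
    path model with geometric moment arms and range-agreement statistics for
    comparison.  Includes parametric synthetic muscle/bone generators with
    closed-form oracles so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
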