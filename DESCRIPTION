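Package: leafedge3d
Title: Curve-Based Three-Dimensional Leaf Edge Reconstruction from Multiview Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs closed three-dimensional leaf edge curves from per-view
    leaf instance masks and known camera projection matrices. Leaf contours are
    extracted from label masks and split into overlapping curve fragments; pairs
    of fragments across nearby views are matched along epipolar bands,
    triangulated into 3D curve fragments, and filtered by multiview reprojection
    support; surviving fragments are grouped into loops (outer edge and holes)
    and each loop is fit with a closed periodic B-spline. Includes a synthetic
    multiview scene generator (virtual leaves, cylindrical camera rigs, occluder
    pillars, ground-truth masks, edges, and labeled point clouds), leaf
    correspondence identification via point-cloud clustering with hidden point
    removal, and evaluation tools: standardized Frechet distance, occlusion
    index, precision-recall sweeps over the support threshold, and a Bayesian
    ridge regression guideline for choosing the support threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    EBImage,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
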