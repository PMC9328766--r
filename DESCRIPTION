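Package: exmorph
Title: Axon Morphometry for Expansion Microscopy Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification of dopamine-axon architecture in
    expansion-microscopy light-sheet volumes. Converts per-voxel axon
    probability maps into binary masks by strict thresholding and
    small-component removal, then computes axon volume fraction, 3D
    skeleton length density and Euclidean-distance-transform axon radius,
    with conversion of image-space measurements to pre-expansion tissue
    units. Also provides a keypoint-based estimator of the linear
    expansion factor from pre-/post-expansion image pairs (similarity
    transform fit with robust consensus), patch/matrix fluorescence-ratio
    analysis of striatal compartments, an optical-fractionator estimator
    of total neuron number, and seeded synthetic phantom generators with
    exact ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    igraph,
    jsonlite,
    tiff,
    png,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
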