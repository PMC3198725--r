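Package: emsynapse
Title: Automated Detection and Segmentation of Synapses in 3D Electron
    Microscopy Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automated detection and voxel-level segmentation of
    asymmetric synapses in nearly isotropic serial electron microscopy
    volumes. Computes a 38-channel bank of 3D geometric image features
    (Gaussian smoothing, gradient magnitude, Laplacian, difference of
    Gaussians, Hessian and structure-tensor eigenvalues at multiple
    scales), trains a random forest voxel classifier from sparse
    brush-stroke labels, converts the synapse probability map into
    segmented candidates by smoothing, hysteresis thresholding,
    connected components and size filtering, and evaluates detections
    against ball-style ground-truth annotations with precision and
    recall. Includes a seeded synthetic EM-volume generator with known
    ground truth, blockwise prediction for large volumes, and an HTML
    proofreading report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    randomForest,
    rhdf5,
    tiff,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
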