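Package: gashap
Title: Genetic-Algorithm Refinement of Shapley Attribution Maps for 3D Image Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Turns voxel-level Shapley attributions of a 3D image classifier
    into an optimized, anatomically interpretable binary region mask.  Voxel
    heatmaps are aggregated over a labelled parcellation atlas into per-region
    scores, percentile-binned into length-R chromosomes over {0,1,2,3}, decoded
    into binary masks by per-region omission, morphological erosion, identity
    or dilation, and refined by a genetic algorithm whose fitness balances
    masked classification accuracy against the number of selected regions.
    Includes NIfTI volume and atlas I/O, a synthetic phantom cohort generator
    with planted signal regions, a small trainable 3D convolutional network
    classifier with input-gradient attribution, exact and permutation-sampled
    Shapley values over voxel groupings, and a one-command pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
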