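Package: ecmshape
Title: Predicting ECM-Driven 3D Invasion from Cell-Adhesion Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify breast-cancer cell responses to extracellular
    matrix (ECM) proteins and to predict three-dimensional spheroid invasion
    from two-dimensional cell-adhesion morphology. Implements the 11 classical
    cell-shape descriptors (area, perimeter, mean radius, Feret diameters,
    aspect ratio, eccentricity, compactness, extent, form factor, solidity)
    from labeled cell masks with border-cell exclusion; 2D migration speed and
    path-ratio persistence from trajectories; spheroid invasion fold change;
    condition-level clustering, k-nearest-neighbour graphs and PCA; discrete
    AdaBoost with decision stumps and AUROC scoring for low/high response
    classification; and NIPALS partial least squares regression with
    leave-one-out Q2, permutation validation, VIP scores and new-condition
    prediction. A synthetic-study generator with a known latent coupling
    between cell shape and migration/invasion supports end-to-end testing and
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    EBImage,
    tiff,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
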