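Package: somatect
Title: Automated Soma Detection in Confocal Images of Neuronal Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Automated detection of the location and morphology of neuronal
    cell bodies (somas) in fluorescence microscopy images of cultured
    neuronal networks. Implements a 2D pipeline on projected confocal
    stacks (shearlet shrinkage denoising, support-vector-machine
    segmentation on multiscale Laplacian features, the Directional Ratio
    coherence statistic, and level-set front propagation with a 3-sigma
    area criterion to separate clustered somas) and a 3D pipeline for thin
    image stacks (deblocking into single-soma substacks, shearlet-based
    surface detection, localized thresholding of the low-contrast bottom
    slices, and volume assembly). Includes a synthetic phantom generator
    with exact ground truth and the validation metrics used in this field
    (true-positive rate, soma-normalized false-positive rate, Dice
    coefficient, and Pratt's figure of merit).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    e1071,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
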