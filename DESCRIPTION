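Package: conefinder
Title: Cone Photoreceptor Detection in Adaptive Optics Ophthalmoscope Images
    with a Convolutional Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects cone photoreceptors in adaptive-optics scanning light
    ophthalmoscope (AOSLO) images with a small patch-based convolutional
    neural network. Training patches are extracted at manually marked cone
    positions, with non-cone examples sampled from the Voronoi edges of the
    markings. The trained network is slid over every pixel to form a cone
    probability map, which is smoothed, thresholded with the extended-maxima
    transform, and reduced to cone centres. Post-processing parameters are
    selected automatically by maximising Dice's coefficient against manual
    markings. Includes one-to-one point matching and agreement metrics
    (true positive rate, false discovery rate, Dice, cone density,
    Bland-Altman limits), and a synthetic cone-mosaic generator for both
    confocal and split-detector appearance with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    tiff,
    png
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
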