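Package: subbasal
Title: Corneal Subbasal Nerve and Dendritic Cell Quantification from In
    Vivo Confocal Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated quantification of corneal subbasal nerve fiber
    length (CNFL) density and dendritic cell (DC) density from in vivo
    confocal microscopy (IVCM) images. Parses NeuronJ tracing (.ndf) and
    Labelme polygon annotation files, rasterizes them into training
    masks, trains small residual U-Net segmentation models and an
    encoder-based nerve-length regressor with a built-in CPU training
    core, estimates per-image nerve length by topology-preserving
    skeletonization with diagonal-weighted link counting, counts cells
    per morphological class by connected components, converts per-image
    quantities to per-participant densities, and evaluates agreement
    (Dice, recall, precision, specificity, MAPE, MAE, Bland-Altman
    limits of agreement, intraclass and Pearson correlation) and group
    differences (Levene's test, pooled t-test, Cohen's d,
    Benjamini-Hochberg adjustment). A synthetic image generator with
    analytically known nerve arc length and cell counts supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    tiff,
    png
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
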