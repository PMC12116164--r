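Package: orchardyield
Title: Apple Yield Estimation from Fused Canopy Structure, Spectral and
    Chlorophyll Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating apple yield in small orchard plots by fusing
    three feature sources: structural ratios of tree organs (flowers, fruits,
    leaves, branches) obtained by semantic segmentation of ground photographs,
    visible and multispectral vegetation indices from four-band reflectance
    rasters, and leaf chlorophyll content (SPAD). Includes an
    attention-augmented DeepLabv3+ semantic segmentation network (CBAM on the
    encoder output, ECA on the decoder's low-level path) implemented natively
    with full training and inference support, segmentation metrics (pixel
    accuracy, class accuracy, mean IoU), image tiling with background-tile
    filtering, twelve vegetation indices with zonal aggregation over plot
    polygons, Pearson feature screening, KNN/PLS/RF/SVM yield regression with
    exact Shapley feature attribution, and a synthetic-orchard generator that
    produces paired images/masks, reflectance rasters and plot records with
    known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    caret,
    e1071,
    jsonlite,
    mixOmics,
    png,
    pracma,
    randomForest,
    stats,
    tiff,
    utils
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
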