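Package: fruitfusion
Title: Multimodal RGB-D Fusion for Fruit Detection in Orchard Scenes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds multi-channel detector inputs from aligned colour images,
    depth rasters and point clouds of orchard scenes. Provides point-cloud
    denoising (voxel downsampling and k-nearest-neighbour statistical outlier
    removal), pinhole 3D-to-2D projection with mirror and offset correction,
    chroma (R-G) and Laplacian edge key-feature extraction with 6:4 weighted
    fusion, composition of 8-channel [R,G,B,F,D,X,Y,Z] images, anchor-box
    adequacy checks with k-means re-estimation and genetic refinement, a
    compact anchor-based single-stage detector with a configurable m-channel
    input layer, precision/recall/F1 evaluation, and a synthetic orchard scene
    generator for end-to-end experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    tiff,
    stats
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
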