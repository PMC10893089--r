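Package: dbmsc
Title: Double-Branch Multi-Scale Contextual Segmentation of Street Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Semantic segmentation of street trees from paired RGB and NDVI
    raster tiles with a double-branch encoder-decoder network. The encoder
    stacks Multi-Scale Contextual (MSC) blocks that fuse parallel dilated
    convolutions with a patch-transformer global path; the decoder gates
    upsampled features with a channel attention mechanism. Includes tile and
    manifest I/O with augmentation, a synthetic street-scene generator for
    fully reproducible experiments, a CPU training loop (Adam, binary
    cross-entropy, reduce-on-plateau), tiled inference over large rasters,
    and pixel-level evaluation (overall accuracy, F1, IoU, Cohen's kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
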