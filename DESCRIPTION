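Package: lifoseg
Title: Optic Disc Segmentation by Local Image Fitting with an Elliptical Shape Prior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments the optic disc in retinal fundus image regions of
    interest with a level-set active contour that minimises a local image
    fitting (LIF) energy augmented by an arc-length penalty and a
    co-evolving elliptical shape prior (the LIFO model). The initial
    contour is extracted automatically from a superpixel cellular-automata
    saliency map followed by mean filtering, Otsu thresholding and
    largest-connected-component selection. Includes pixelwise evaluation
    metrics (Jaccard overlap, precision/recall/F-score, success rate), a
    deterministic generator of fundus-like synthetic fixtures with known
    ground truth (vessel occlusions, intensity inhomogeneity,
    peripapillary-atrophy-like rings), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rcpp,
    grDevices,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
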