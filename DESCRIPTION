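Package: ki67pi
Title: Ki67 Proliferation-Index Quantification via Proximity-Map Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects Ki67-positive (DAB brown) and Ki67-negative (hematoxylin
    blue) tumour nuclei in stained breast-tissue images with a compact U-Net
    that regresses per-class Gaussian proximity maps, then decodes nuclei
    centres by Otsu thresholding and watershed separation and computes the
    proliferation index (PI) for patches, tissue microarrays and whole-slide
    images (hotspot rule). Includes a seeded synthetic stained-image
    generator with exact ground truth, the ideal/non-ideal weak-supervision
    data-partition protocol, four regression losses, whole-slide tissue
    masking and tiling, and detection/PI validation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, yaml, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
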