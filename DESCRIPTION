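Package: msxfruit
Title: Apple Fruit Recognition in Multi-Spectral Dynamic (MSX) Pseudo-Color Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects apple fruit regions in pseudo-color thermal (MSX) canopy
    images. Implements a color-based pre-processing chain (red-component
    grayscale, Otsu binarization, disk-element morphological opening,
    small-area removal, region labeling, pseudo-color restoration),
    per-region gray-level co-occurrence matrix (GLCM) texture features
    (direction-averaged contrast, entropy and correlation over minimum
    bounding rectangles), a linear maximum-margin region classifier, and
    pixel-overlap evaluation metrics (recognition precision, sensitivity and
    relative error) stratified by complete versus incomplete fruit regions.
    Includes a synthetic-scene generator with ground-truth masks and
    annotations for end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    jpeg,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
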