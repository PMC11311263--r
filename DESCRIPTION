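Package: mammocalc
Title: Microcalcification Detection and Localization in Mammogram-Like Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A hybrid pipeline for detecting and localizing microcalcifications
    (small bright calcium deposits, 0.1-1 mm) in mammogram-like grayscale images.
    Combines classical descriptive feature extraction (Prewitt edge kernels, a
    five-orientation Gabor filter bank, windowed gray-level co-occurrence matrix
    texture) with a small convolutional binary classifier, and localizes candidate
    deposits with the white top-hat morphological transform. Ships a synthetic
    phantom generator with exact ground truth so the whole pipeline is testable
    without clinical data, plus preprocessing (grayscale conversion, intensity
    windowing, largest-island artifact removal, resizing), geometric augmentation,
    stratified splitting, and evaluation (confusion-matrix metrics, ROC/AUC,
    localization scoring).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
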