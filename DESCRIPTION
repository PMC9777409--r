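Package: lesionfuse
Title: Hybrid Hand-Crafted and Deep Feature Fusion for Skin Lesion Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A testable implementation of a hybrid skin-lesion classification
    pipeline for dermoscopic-style images. Images are denoised with a Gaussian
    filter, described by two feature branches (a 256-bin local binary pattern
    texture histogram and a pluggable convolutional feature extractor trained
    with label-smoothing cross-entropy and Adam), fused by concatenation,
    reduced by entropy-based feature selection, and classified as benign or
    malignant by a small LSTM network. Includes a seeded synthetic lesion-image
    generator emulating a balanced two-class dermoscopy corpus so the whole
    pipeline is exercisable without any dataset download, plus
    confusion-matrix, precision/recall/F1 and ROC/AUC evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jpeg,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    numDeriv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
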