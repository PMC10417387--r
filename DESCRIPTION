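Package: dermlight
Title: Lightweight Dermoscopy Lesion Classification with Hue-Preserving
    Perceptual Contrast Enhancement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for nine-class pigmented skin lesion
    (PSL) classification from dermoscopy images. Implements hue-preserving
    contrast enhancement in the perceptual CIECAM02 (JCh) colour space, a
    compact SqueezeNet-style convolutional network whose fire modules use
    depthwise-separable 3x3 expand paths ("spark" modules) with batch
    normalization and GELU activations, AdaBelief optimization with
    weighted cross-entropy, class-balancing augmentation, stratified
    k-fold splitting, and a macro-averaged multiclass evaluation suite
    (accuracy, precision, recall, specificity, F1, MCC, one-vs-rest AUC).
    A synthetic dermoscopy image generator provides deterministic,
    class-separable fixtures so the whole pipeline is testable without
    clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
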