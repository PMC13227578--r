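Package: fetalvit
Title: Dual-Head Vision Transformer for Fetal Ultrasound Classification and Severity Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pure-R implementation of a patch-based Vision Transformer for
    grayscale fetal-ultrasound-style images with two output heads: a softmax
    classification head for fetal health status and an affine regression head
    for a continuous severity score. Includes image preprocessing (resizing,
    min-max normalization, deterministic seeded augmentation), composite-loss
    training with Adam and early stopping, attention-rollout saliency maps
    with a battery of attention-alignment metrics (centre-of-gravity shift,
    attention focus ratio, weighted relevance score, attention energy
    distribution, overlap dynamics, IoU/DSC), a statistical evaluation suite
    (classification report with Cohen's kappa, regression errors, confidence
    intervals, Cohen's d), ablation and hyperparameter sweep harnesses, and a
    seeded speckle-phantom generator that emulates annotated ultrasound data
    so the whole pipeline runs without any clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
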