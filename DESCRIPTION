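Package: drsaliency
Title: Saliency-Map Evaluation for CNN-Based Diabetic Retinopathy Grading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies which ocular image features convolutional
    neural-network graders of diabetic retinopathy actually attend to.
    Provides a seeded synthetic fundus generator with exact per-component
    ground-truth masks (microaneurysms, hemorrhages, exudates, optic disc,
    vessels), a zoo of small trainable CNN grade classifiers exposing the
    internals that gradient-weighted class activation mapping (Grad-CAM)
    requires, Grad-CAM and occlusion-sensitivity saliency maps, Otsu
    binarization, intersection-over-union scoring of saliency against
    component masks, inter-model agreement matrices, missed-pathology
    rates, and a five-grade classification metric suite (accuracy, AUC,
    Cohen's kappa, Matthews correlation, per-grade sensitivity and
    specificity), orchestrated end-to-end behind one pipeline entry point.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    pROC,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    e1071
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
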