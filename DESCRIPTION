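Package: rccgrade
Title: Noise-Robust Deep Learning for Binary Grading of Clear Cell Renal
    Cell Carcinoma from CT Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A backbone-agnostic pipeline for binary Fuhrman grading
    (low vs high grade) of clear cell renal cell carcinoma from
    per-patient stacks of cropped tumour CT images. Implements rotation
    self-supervised pretraining, a mixed cross-entropy loss against
    one-directional label noise, class-frequency sample reweighting,
    patient-level max aggregation of image scores, and decile-stripped
    AUC model ensembling, together with a seeded synthetic cohort
    generator, manifest I/O, temporal cohort splitting, and ROC/AUC
    evaluation. The small convolutional backbone and its SGD trainer are
    implemented in C++ via RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
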