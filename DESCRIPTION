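Package: stagevit
Title: Ordinal Severity Grading of Lesion Images with a Stage-Aware Vision Transformer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a vision-transformer classifier for ordinal
    malignancy-risk grading of endoscopic still images, extended with a
    progression-aware sequential feature learner over the four ordinal risk
    stages (Benign, Low-Risk, High-Risk, Malignant), a dual output head
    producing both a categorical class and a continuous risk score in [0,1],
    Score-CAM attribution over the final-block token maps with heatmap-mask
    concordance scoring, and the matching evaluation suite (support-weighted
    classification metrics, one-vs-rest and micro-averaged ROC AUC,
    risk-score monotonicity, ablation harness). A synthetic-lesion image
    generator with ground-truth masks provides desk-scale ordinal datasets
    for end-to-end exercise of the pipeline. The forward and backward passes
    of the network are implemented in base R matrix algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
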