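Package: vegdet
Title: Lightweight Attention-Based Detection of Protected-Vegetable Diseases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-implementation of VegetableDet, a lightweight
    object-detection framework for greenhouse (protected) vegetable disease
    monitoring. The package provides a deformable-attention transformer (DAT)
    augmented backbone, a feature-pyramid neck enhanced with a channel-spatial
    adaptive attention mechanism (CSAAM), an anchor-free detection head with a
    composite IoU/classification/objectness loss, a two-stage transfer-learning
    trainer with tiered per-partition learning rates, class-balanced offline
    augmentation planning with Mosaic composition, PASCAL-VOC annotation I/O
    with the study's labelling filters, and a full precision/recall/AP/mAP
    evaluation suite with k-fold cross-validation drivers. A deterministic
    synthetic greenhouse-scene generator with exact ground truth makes every
    stage testable on a CPU without any external dataset. All neural-network
    computation (reverse-mode automatic differentiation, Adam) is implemented
    in base R.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    xml2,
    jsonlite,
    yaml,
    png,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
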