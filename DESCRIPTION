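Package: pestfsod
Title: Few-Shot Pest Object Detection with Feature Aggregation and
    Supervised Contrastive Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully tested implementation of a few-shot object
    detection (FSOD) pipeline for agricultural pest scenes. Provides a
    procedural synthetic-scene generator that emulates the statistical
    structure of small imbalanced pest detection benchmarks (COCO JSON
    output, multi-scale targets, cluttered backgrounds), base/novel class
    splits and K-shot episode construction, a cross-attention feature
    aggregation module that enriches query RoI features with support
    features, a class-weighted supervised contrastive loss on projected
    unit-norm embeddings, a multi-task objective combining focal
    classification loss, smooth-L1 box regression and an attention
    entropy/sparsity regularizer, a two-stage (base training plus K-shot
    fine-tuning) detector with analytic gradients, and matching-based
    evaluation (per-class AP, bAP/nAP/mAP, PR curves, confusion matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
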