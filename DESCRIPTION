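Package: leafdistill
Title: Multistage Knowledge Distillation for Lightweight Plant-Disease Detectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and trains lightweight anchor-based one-stage detectors for
    multi-crop, multi-disease lesion detection, and improves them by multistage
    knowledge distillation from a larger frozen teacher detector. Provides the
    detector primitives (IoU, CIoU loss, NMS, k-means anchor estimation, head
    decoding), the stage-wise distillation losses (attention-guided focal and
    global feature imitation at the backbone and neck, diversity knowledge
    transfer at the head), the supervised detection loss and combined objective,
    declarative architecture builders with a structural audit (convolution
    census, parameter and FLOP counts), mAP evaluation, Pascal-VOC/COCO
    annotation I/O with a label-cleaning pass, and a seeded synthetic
    lesion-scene generator so the whole pipeline runs end-to-end at desk scale
    on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    xml2,
    yaml,
    png,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
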