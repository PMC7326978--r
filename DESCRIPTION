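Package: berryfield
Title: Blueberry Cluster Trait Extraction and Instance-Segmentation Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Extracts fruit traits (berry count, maturity ratio, cluster
    compactness) from per-berry instance segmentations of blueberry branch
    images, classifies per-berry maturity objectively from HSV Hue, and
    evaluates segmentation quality with COCO-style average precision over
    mask IoU thresholds, mean mask IoU, and a four-way detection-error
    taxonomy (one-as-two, missed, two-as-one, partial). Reads and writes
    VGG Image Annotator 2.x polygon projects and a simple detection JSON,
    quantifies manual-correction rounds of an iterative annotation loop,
    and calibrates detected counts against ground truth by linear
    regression. A synthetic berry-cluster scene generator with exact
    ground truth (full and visible masks under z-order occlusion) makes
    the whole pipeline testable without field images.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    grDevices,
    utils,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
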