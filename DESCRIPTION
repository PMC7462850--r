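Package: wsiscreen
Title: Whole-Slide Prostate Cancer Screening with Segmentation Networks and
    Style Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for whole-slide image (WSI) classification of
    prostate biopsies. Trains multi-class semantic-segmentation networks (U-Net,
    fully-convolutional DenseNet) and a patch classifier on sparsely annotated
    patches, produces whole-slide tumor likelihood maps by tiled inference over
    tissue, aggregates them into a slide-level score (the T07 statistic, with
    minimum-redundancy maximum-relevance feature selection), and evaluates
    slide-level performance with ROC/AUC, bootstrap confidence intervals and
    fixed operating points. A cycle-consistent adversarial network normalizes
    scanner/stain style between cohorts. Includes a synthetic multi-center slide
    generator so the full pipeline is testable without clinical data. The neural
    network machinery (reverse-mode autodiff over convolutional layers) is
    implemented in base R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    stats,
    tiff,
    utils,
    grDevices,
    graphics,
    xml2
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
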