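Package: growthmap
Title: Growth-Pattern Mapping of Lung Adenocarcinoma Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A whole-slide-image analysis pipeline that classifies lung
    adenocarcinoma tissue into five classes (acinar, micropapillary, solid,
    cribriform, non-tumor). Provides tissue masking at low magnification,
    tile-grid construction with cross-scanner physical-area matching,
    Reinhard color transfer in the decorrelated log-chromatic (l-alpha-beta)
    space, k-means derivation of target color patterns, color-by-orientation
    tile augmentation, a pluggable tile-classifier contract with a
    deterministic texture-feature backend and a small trainable neural
    backend, contextual soft-voting over nine overlapping glimpses,
    tumor-map quantification in 5 percent increments, and slide/set/study
    level evaluation against pathologist annotations (Aperio ImageScope
    XML). A seeded synthetic-slide generator makes every stage testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    nnet,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
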