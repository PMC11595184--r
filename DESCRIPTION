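Package: cellpaintr
Title: Feature- and Deep-Learning-Based Cell Painting Analysis of
    Macrophage Polarization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open high-content screening toolkit for quantifying
    macrophage (re-)polarization from four-channel cell painting images
    (Hoechst33342, Alexa488, Alexa568, Alexa647). Provides nucleus and
    cell-body segmentation, a 1279-entry per-cell feature catalog
    (intensity, SER and Gabor texture, standard and STAR morphology over
    nucleus, cytoplasm and full-cell regions), the cell-roundness Z-score
    read-out against DMSO vehicle wells with cell-count toxicity flagging,
    per-well PCA fingerprints, a trained sparse linear classifier producing
    DMSO-normalized %M2(-like)-%M1(-like) scores with relevant-feature and
    morphology-ablation reports, and a compact convolutional classifier
    with confidence gating. A seeded synthetic-plate simulator with known
    per-well class mixtures makes every stage testable without access to
    proprietary imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    glmnet,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    arrow,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
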