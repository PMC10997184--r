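Package: facetropism
Title: Facet Joint Angle Measurement and Facet Tropism Analysis from Axial
    Lumbar Spine Label Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semiautomatic measurement of lumbar facet joint orientation from
    axial slice segmentation masks. Extracts the six anatomical landmarks
    (anterior/posterior facet endpoints left and right, vertebral body center,
    spinous process) from four-class label masks, computes the left and right
    facet joint angles against the midline and their signed asymmetry,
    classifies facet tropism at literature thresholds, and summarises cohorts
    (per-level, per-sex means, prevalence). Ships the full evaluation
    machinery: overlap (Dice, IoU) and surface-distance (ASD, 95th-percentile
    Hausdorff) segmentation metrics, nonparametric Bland-Altman rater
    agreement, coefficient of determination, normality gates, and a desk-scale
    multi-class segmentation trainer using the Generalized Dice Loss with
    participant-level cross-validation. A synthetic axial-slice phantom
    generator with analytic ground truth makes every stage testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
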