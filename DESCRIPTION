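Package: albudget
Title: Dynamic-Budget Superpixel Querying for Active Learning in
    Semantic Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Regional active learning for semantic segmentation with a
    dynamic per-image labeling budget.  Images in the unlabeled pool are
    ranked by Monte-Carlo BALD (Bayesian Active Learning by Disagreement)
    uncertainty, each selected image is over-segmented into SLIC
    superpixels, and a two-class Jenks natural-breaks split of the
    per-superpixel uncertainty scores decides how many regions to query
    in that image.  A budget-matched static top-q baseline, a
    foreground-only querying mode for background-dominant field imagery
    (vegetation-index and model-prediction foreground masks), a
    simulated-oracle active learning loop with pluggable learners, a
    seeded synthetic field-image generator, and mean-IoU evaluation are
    included, so the full pipeline runs on CPU with no external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    nnet,
    png,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
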