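Package: cafpabayes
Title: Interpretable Bayes Classification for Audiological Decision Support
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Clinical decision support for audiology built on the Common
    Audiological Functional Parameters (CAFPAs), an interpretable layer of
    ten values in [0,1] describing a patient's auditory system. Fits
    per-category beta training distributions to labeled CAFPA vectors,
    classifies patients between diagnostic categories by weighted sums of
    probability densities (a Bayes decision on each comparison set), searches
    all binary CAFPA combinations scored by the Youden index, derives
    relative-frequency weights from high-performing combinations, propagates
    binary decisions through two-level tree sets to three terminal categories
    with a per-decision certainty measure, and predicts CAFPAs from
    audiological measurement batteries by cross-validated penalized
    regression or random forests. Includes a seeded synthetic-cohort
    generator so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    fitdistrplus,
    glmnet,
    ranger,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
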