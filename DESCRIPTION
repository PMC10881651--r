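Package: sproutscreen
Title: Phenotypic Analysis of Angiogenic Sprouting Screens on Microfluidic Chips
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of high-content angiogenesis screens run in
    microfluidic organ-on-a-chip plates. Detects nuclei in chip fluorescence
    images (rolling-ball background subtraction, difference-of-Gaussians
    enhancement, IsoData thresholding, watershed separation), quantifies
    sprouting by the mean distance of the ten furthest sprout nuclei, scores
    chips with robust Z* statistics against vehicle controls, applies a
    three-gate duplicate-agreement hit-calling procedure with vessel-toxicity
    exclusion, summarizes hit pathways by unique pathway-combination
    frequency, and fits four-parameter logistic dose-response curves for IC50
    estimation. Ships a calibrated synthetic screen generator (plate layouts,
    compound libraries with planted effects, rendered nuclei images with
    ground truth) so the full pipeline can be exercised and validated without
    proprietary screen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    EBImage,
    tiff,
    minpack.lm,
    yaml,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
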