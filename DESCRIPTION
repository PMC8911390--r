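Package: octafract
Title: Fractal Morphometry of Neovascular Networks on OCT Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative morphometry of choroidal neovascular lesions on
    en-face optical coherence tomography angiography (OCT-A) slabs.
    Implements the full measurement pipeline: Otsu binarization, median
    despeckling, small-component removal, density-map lesion localization,
    lesion area and vascular perfusion density, topology-preserving
    skeletonization, multi-origin box-counting fractal dimension and
    gliding-box lacunarity, together with the cohort statistics (group
    summaries, two-sample t-tests, Pearson correlation) used to compare
    type 1 choroidal neovascularization with polypoidal choroidal
    vasculopathy. Ships synthetic generators for canonical fractals of
    known dimension, branching vascular networks with polyp-like terminal
    dilations and multiplicative speckle, and cohort tables, used to
    validate every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    png,
    tiff,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
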