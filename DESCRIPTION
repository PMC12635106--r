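Package: holomass
Title: Bacterial Dry Mass and Morphology from Quantitative Phase Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of single-bacterium dry mass from digital
    holographic microscopy phase images. Converts phase maps to optical path
    difference (OPD), levels smooth background aberrations with a 2-D
    polynomial surface fit on a discrete-orthonormal total-degree basis,
    suppresses high-frequency noise with Gaussian filtering, segments cells
    by Gaussian-weighted adaptive thresholding with morphological
    refinement, and integrates OPD per region into dry mass with fully
    propagated uncertainty (OPD noise, refractive-index increment, and
    mask-area terms). Downstream tools classify cocci as singles or
    clusters by Gaussian-mixture modelling of circularity with AIC/BIC
    model selection, regress bacillus length on mass, fit the
    Koch-Schaechter steady-state size distribution to recover the mean
    division mass, and compare mass distributions by the one-dimensional
    Earth Mover's Distance with bootstrap. A synthetic-scene generator with
    analytic per-cell ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: CellBiology, Microscopy, Segmentation, Classification, Software
RoxygenNote: 7.3.3
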