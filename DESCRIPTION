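Package: myoquant
Title: Multiscale Quantification of Cardiac Ultrastructure from Volume
    EM and Micro-CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for correlative multiscale cardiac imaging:
    serial block-face scanning electron microscopy (SBF-SEM) image stacks
    and micro-CT label volumes. Provides seeded synthetic phantoms with
    ground-truth labels and per-myofibril orientation tables; translation
    stack alignment by normalized cross-correlation; per-slice non-local
    means denoising; affine intensity matching; intensity-threshold
    segmentation of extracellular space with morphological cleanup and a
    pixelwise accuracy evaluator; organelle volume-fraction stereology
    (S_E/S_T and S_i/(S_T - S_E)); per-myofibril transmural and elliptical
    angle estimation with 18-bin histograms and linear or circular-axial
    summaries; ventricular lumen volume ratios; and landmark-based
    similarity registration between micro-CT and EM coordinate frames.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
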