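Package: mqpi
Title: Multiparametric Quantitative Phase Imaging Drug-Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for label-free drug-response profiling of
    single cells by differential phase contrast (DPC) quantitative phase
    imaging. Reconstructs phase maps from half-circle illumination
    intensity images by Tikhonov-regularized inversion, segments cells and
    integrates dry mass via the specific refractive increment, links cells
    into tracks, derives specific growth rates (SGR), fits Hill
    dose-response curves (EC50, depth of response), computes
    Hellinger-distance time-of-response statistics, and decomposes SGR
    distributions into responsive and non-responsive subpopulations with a
    sequentially initialized two-Gaussian mixture. Includes a seeded
    synthetic-data generator producing mass tracks, phase movies, and raw
    DPC intensity stacks for validation without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    EBImage,
    clue,
    mclust,
    minpack.lm,
    tiff,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
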