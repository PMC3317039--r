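Package: punctate
Title: Confocal Puncta Quantification and Image-Based Subcellular Fractionation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Quantifies receptor immunolabel in multi-channel confocal
    z-stacks. Implements control-derived thresholding and pixel
    colocalization with a presynaptic marker for neuropil-level measures,
    selection of the maximal-colocalization plane and rasterization of a
    fixed-physical-thickness membrane band around the traced soma outline
    (an image-based subcellular fraction) that partitions receptor signal
    into synaptic and extrasynaptic pools, fixed-iteration Richardson-Lucy
    deconvolution, a ground-truthed synthetic scene and cohort simulator
    with a configurable dose-response model, and the accompanying
    statistical battery: mixed-design ANOVA, Tukey post-hoc contrasts,
    ANCOVA adjustment for total signal, and quantitative western-blot
    normalization arithmetic.
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
    withr,
    readr,
    yaml,
    ggplot2,
    generics,
    tiff,
    EBImage,
    igraph,
    lme4,
    lmerTest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
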