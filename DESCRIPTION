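Package: holomito
Title: Holographic Microscopy Assay for Mitochondrial Permeability Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for a label-free holographic
    (refractive-index) plus TMRM fluorescence assay of the mitochondrial
    permeability transition. Provides a forward simulator of dual-channel
    time-lapse movies with per-organelle ground truth, pixel classification
    and threshold segmentation of mitochondria in refractive-index images,
    baseline-defined ROI quantification with FCCP-anchored normalization of
    the TMRM signal, single-organelle tracking with depolarization-onset and
    permeabilization event detection, and condition-level summary statistics
    (mean +/- SEM, ANOVA, t-tests). Results are returned as tidy tibbles and
    plotted with ggplot2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tiff,
    EBImage,
    ranger,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
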