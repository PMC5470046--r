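Package: sgquant
Title: Quantitative Imaging Analysis of Stress Granules and Their
    Aberrant, Misfolded-Protein-Containing States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for quantifying stress granule
    (SG) biology from fluorescence microscopy: granule segmentation on a
    marker channel, per-granule relative-enrichment ratios (mean intensity
    inside the granule over mean intensity in a surrounding region) with
    threshold classification and cross-channel correlation, FRAP
    double-normalization and single-exponential mobile-fraction fitting,
    pixel-level colocalization with a Costes block-randomization null,
    particle tracking with fusion/fission event calling, RNase-sensitivity
    area quantification, and Kaplan-Meier/log-rank analysis of per-cell
    time to complete SG disassembly. Includes a fully ground-truthed
    synthetic-microscopy generator (diffraction-blurred granules,
    Poisson + Gaussian camera noise, scripted time-lapse events, FRAP
    recovery with known mobile fraction) against which every analysis
    stage is validated.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
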