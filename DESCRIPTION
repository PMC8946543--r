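Package: nucoloc
Title: Nuclear Chromatin and Colocalization Analysis for Confocal Z-Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of Schwann-cell nuclei in multi-channel
    confocal z-stacks: 3D nuclear segmentation from the DAPI channel,
    euchromatin/heterochromatin classification by DAPI intensity, peripheral
    versus central signal profiling along longitudinal and transverse nuclear
    vectors, five-way colocalization analysis (Manders split coefficients,
    Spearman and Kendall rank correlations, Costes block-scrambling
    randomization), and nonparametric genotype comparison with medians and
    bootstrap confidence intervals. Includes a ground-truthed synthetic scene
    generator emulating wild-type and Trembler-J phenotypes so the whole
    pipeline is testable without microscope data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
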