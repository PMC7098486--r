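Package: ubiquant
Title: Quantitative Analysis of Ubiquitin Proteoforms and Mitochondrial
    Ubiquitylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative proteomics of PINK1/Parkin-driven
    mitophagic signaling: exact-mass and isotope-envelope models of
    phosphorylated and diGLY-branched ubiquitin proteoforms released by
    Ub clipping, simulation and averagine-based deconvolution of intact-mass
    profile spectra with extracted-ion-chromatogram quantification, TMT-MS3
    reporter-ion filtering, rollup and normalization for proteome, diGLY and
    phospho layers, moderated Welch tests with permutation-based FDR control,
    and quantification of mitophagic flux reporters and PRM/AQUA absolute
    stoichiometry. Every input the pipeline consumes can be simulated with
    known ground truth for round-trip validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
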