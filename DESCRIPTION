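Package: nucleostress
Title: Quantification of Nucleolar Stress Phenotypes and G4-Associated
    Gene Program Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-cell quantification of nucleolar-stress phenotypes from
    three-channel fluorescence microscopy (DNA / NPM1 / fibrillarin):
    nucleus and nucleolus segmentation, nucleolar-cap detection and sizing,
    nucleoplasmic fibrillarin focus counting, and rule-based phenotype
    classification with per-sample proportions.  Companion gene-program
    tools build intersection-defined gene sets from differential-expression
    tables, annotate promoter-proximal G-quadruplex formation from BED
    interval collections (TSS +/- flank windows), compute interactome
    convergence across protein sets, and provide Welch's t-test and
    delta-delta-Ct relative qPCR reporting.  A fully ground-truthed
    synthetic-data generator produces images, gene tables, interval
    fixtures and protein lists with planted phenotype mixtures and set
    cardinalities for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
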