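Package: pepsmd
Title: Statistical Molecular Design and SAR Analysis for Anchor-Modified
    Peptide Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and analysing anchor-substituted peptide
    libraries against class II MHC proteins. Implements post-docking
    geometric filtering of peptide poses by backbone RMSD, per-position
    consensus scoring over multiple docking scoring functions,
    principal-property statistical molecular design with D-optimal subset
    selection via Fedorov exchange, indicator-variable PLS regression with
    leave-one-out cross-validation and permutation validation, and PCA of
    combined biological response panels. Ships the transcribed MHC binding
    and T-cell response tables for the CII259-273 glycopeptide library and
    a synthetic-data module that emulates docking scores, molecular
    descriptors, poses, and binding responses for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    bio3d,
    jsonlite,
    knitr,
    mixOmics,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
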