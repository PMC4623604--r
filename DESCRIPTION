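Package: idpfrag
Title: NMR Fragment-Screening Analysis for Intrinsically Disordered Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for analysing NMR-based fragment
    screens against intrinsically disordered protein targets such as the
    cell-cycle regulator p27Kip1. Covers fragment-library curation (validity
    and reactive-substructure filters, Murcko scaffold abstraction with alpha
    atoms, Rule-of-Three checks, complexity ranking), chemical-shift
    perturbation significance analysis and binding-site classification,
    global 1:1 fast-exchange dissociation-constant fitting with Monte-Carlo
    uncertainty, ratiometric displacement and fluorescence-anisotropy /
    dose-response analysis, ternary competition equilibria, and two-state
    classification of pairwise-distance dynamics from molecular-dynamics
    trajectories. Includes seeded synthetic-data generators that emulate the
    statistical structure of each input so every stage is testable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    minpack.lm,
    bio3d,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
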