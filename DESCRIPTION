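Package: zincys
Title: Cysteine Thiol Reactivity, Zinc Protection and Crosslink Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for characterising a reactive protein
    cysteine and its modulation by divalent cations, built around the single
    cysteine (Cys328) of vimentin. Estimates thiol pK_a from pH-dependent
    alkylation kinetics (per-well sigmoid fits, ln(Ft/Fo) slopes, and
    Henderson-Hasselbalch titration fits with AICc model selection),
    quantifies cation protection against alkylation and crosslinking from
    gel densitometry tables (band-intensity ratios, percent inhibition,
    spacer-arm trend analysis), estimates apparent zinc affinity from
    chelator competition assays via an explicit mass-balance equilibrium
    model, and classifies cysteine crosslink feasibility and metal-ion
    contact persistence from PDB structures and multi-model trajectories.
    A seeded synthetic-data generator emulates plate-reader kinetics, gel
    densitometry, competition titrations and toy structures so that every
    analysis is testable end to end.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
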