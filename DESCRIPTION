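Package: filafrag
Title: Fragmentation-Driven Life Cycles of One-Dimensional Cell Filaments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of one-dimensional multicellular
    filaments that grow by binary fission and reproduce by fragmentation.
    Fragmentation can be driven by intrinsic cell-level information (cell
    age, age of cell-cell connections, the concentration of a diffusible
    compound, or mechanical stress), by stochastic baselines, or by Boolean
    (AND/OR) combinations of two cues. The package calibrates rule
    thresholds to a target adult size, classifies each fragmentation event
    into one of five reproduction modes (unicellular propagule, equal or
    unequal binary split, complete dissociation, other), summarises
    adult-size distributions and mode frequencies, enumerates the
    integer-partition space of offspring allocations, and ships a small
    command-line interface for batch simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
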