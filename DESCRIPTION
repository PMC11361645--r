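Package: gtpasekin
Title: Nucleotide Exchange and Hydrolysis Kinetics for Small GTPases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and fitting of stopped-flow nucleotide
    association/dissociation fluorescence traces and HPLC GTP-hydrolysis
    time courses for small GTPases of the ARF/ARL family; derivation of
    k_on, k_off, K_d and k_cat with standard errors and kinetics summary
    tables with fold changes; a three-state nucleotide-cycle model
    (free / GDP-bound / GTP-bound) with closed-form steady state, an ODE
    oracle and a classical versus non-classical (GTP-loaded)
    classification; and intensity-based (Pearson, overlap) and
    object-based (centroid-distance) colocalization statistics with a
    ground-truth synthetic image generator. Ships the published rate
    constants for the Arabidopsis ARL2-like GTPase TTN5 and its T30N and
    Q70L variants as a worked data set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
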