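Package: aeropattern
Title: Oxygen-Driven Aggregation and Pattern Formation in Worm Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models collective aggregation and Turing-like pattern formation
    in dense Caenorhabditis elegans populations driven by oxygen-dependent
    motility. Couples a Keller-Segel-type worm-density equation, with
    motility-derived diffusivity and an aerotactic coupling coefficient, to
    surface-oxygen kinetics (diffusion, air penetration, consumption).
    Provides the closed-form linear stability theory (dispersion relation,
    instability criterion, unstable band, critical densities, phase
    diagrams), a conservative finite-volume simulator on a periodic 2-D
    grid, pattern morphology metrics (dots/stripes/holes classification,
    structure spectra, coarsening curves), calibration estimators that
    recover every model parameter from observations, and seeded synthetic
    data generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    generics,
    rlang,
    jsonlite,
    yaml,
    igraph,
    deSolve,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
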