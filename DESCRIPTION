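Package: megamapr
Title: Operational Modes of Place-Cell Attractor Networks Under Conflicting Inputs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of the megamap model, a quasi-continuous
    attractor network of hippocampal place cells with multiple Poisson-distributed
    place fields per cell. Provides threshold-linear firing-rate dynamics with
    global feedback inhibition, delta-rule (optimal) and Hebbian weight
    construction with incremental region-by-region learning, an a-priori
    eigenvalue test for the winner-take-all versus combinatorial operational
    mode, an exact reduction to a two-unit model, and a complete fixed-point,
    bifurcation (Types I-IV), hysteresis and amplification analysis of the
    reduced model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
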