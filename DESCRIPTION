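Package: crnkit
Title: Stochastic Reaction Network Generation and Variable-Condition
    Mass-Action Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated construction of chemical reaction networks (CRNs) by
    stochastic graph-move sampling on molecular connectivity matrices, with a
    graph restraining potential for embedding product graphs in 3D, direct and
    kinetics-guided iterative network exploration, and long-time-scale
    mass-action kinetic simulation of the resulting networks under variable
    experimental conditions.  Includes continuous and discrete rate-update
    integration of stiff reaction rate equations with analytic Jacobians,
    chunked time accumulation, slow-reaction pruning, diffusion-limited rate
    capping, Arrhenius and collision-theory rate calculators, and deterministic
    synthetic fixtures (toy reversible networks, surrogate bond-energy
    kinetics, random stiff networks) so the full workflow runs with no
    external data.
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
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
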