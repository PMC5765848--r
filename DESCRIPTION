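Package: gradsense
Title: Splitting Probabilities and Source Recovery for Brownian Fluxes to
    Small Absorbing Windows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diffusive gradient sensing in unbounded planar
    domains. Computes steady-state splitting probabilities of Brownian
    particles emitted by a point source and captured by small absorbing
    windows on the boundary of a half-plane, an obstacle disk in free
    space, or a disk inside a reflecting strip, using matched-asymptotic
    Neumann-Green's function expansions. Provides a hybrid
    analytical-stochastic simulator that injects and re-injects
    trajectories through exact exit (harmonic-measure) distributions so
    that unbounded Brownian excursions never have to be tracked, and
    inverts measured window fluxes to recover the source location,
    including flux-perturbation uncertainty regions and distance-flux
    maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
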