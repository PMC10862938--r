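Package: diffsse
Title: Diffusion Approximations for State-Dependent Diversification Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Forward-in-time simulation of species state counts and frequencies
    under cladogenetic state-dependent speciation-extinction (ClaSSE) models,
    with emphasis on the geographic-state model (GeoSSE).  Provides the
    infinitesimal mean and variance of the count and frequency diffusions,
    Euler-Maruyama path simulation, an exact continuous-time jump-process
    reference simulator, large-N stationary state-frequency theory (closed-form
    two-region solution, projection-matrix eigenvector method, solving rates
    from target frequencies), mixing-time computation, and a statistical
    harness for comparing simulation ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
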