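Package: svpool
Title: Synaptic Vesicle Pool Kinetics and Miniature EPSC Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling synaptic vesicle cycling as a single-pool
    three-state linear compartment model (ready, fused, recycling), for
    simulating the staged lysophosphatidic-acid (LPA) perturbation of the
    exocytosis and recycling rates, and for analysing the observables that
    report on the cycle: miniature EPSC event trains (inhomogeneous Poisson
    simulation, binning, frequency ratios, cumulative amplitude
    distributions), SynaptopHluorin fluorescence traces (single-exponential
    decay fits), ratiometric calcium traces (top-five peak quantification),
    and Boltzmann dose-response curves (EC50 estimation). Includes exact
    piecewise-constant propagation of the kinetic model via the matrix
    exponential, maximum-likelihood recovery of perturbation parameters from
    event trains, seeded synthetic-data generators for every input the
    pipeline consumes, and a JSON-configured command pipeline with
    reproducible CSV/JSON outputs.
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
    tidyr,
    tools,
    utils,
    withr
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
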