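Package: tissuesim
Title: Agent-Based Multicellular Simulation with Multi-Substrate Biotransport
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An off-lattice, center-based agent-based simulator for
    multicellular systems coupled to a finite-volume multi-substrate
    reaction-diffusion solver. Implements first-order operator splitting
    with a locally one-dimensional (LOD) implicit diffusion-decay step
    solved by a cached-forward-sweep Thomas algorithm; cell mechanics on a
    spatial interaction grid with second-order Adams-Bashforth position
    updates; oxygen-dependent tumor growth with necrosis and apoptosis; a
    stochastic cancer-immune interaction model (biased random-walk
    chemotaxis, attachment, killing, and detachment hazards); and a local
    failure-tolerant parameter-sweep harness with replicate seeding and
    metric aggregation. Includes 2-D hypoxia and tumor-immune study
    configurations, snapshot CSV/SVG output, and heatmap summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    parallel,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
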