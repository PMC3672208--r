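Package: n2ospatial
Title: Bayesian Spatial Modelling and Model Averaging of Chamber Nitrous
    Oxide Fluxes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits Bayesian regression models for replicated, point-referenced
    chamber measurements of soil nitrous oxide (N2O) fluxes under three
    spatial correlation structures: independent errors, a geostatistical
    exponential-decay Gaussian process, and an intrinsic conditional
    autoregressive (ICAR) prior on Thiessen-polygon neighbourhoods. Models
    are fitted by bespoke MCMC, compared by the deviance information
    criterion (DIC), and combined by DIC-weighted Bayesian model averaging.
    Includes Thiessen (Voronoi) adjacency construction for irregular point
    layouts, ordinary kriging of posterior predictions onto a regular grid,
    and a synthetic-data generator that emulates a replicated pasture
    chamber study for end-to-end testing without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
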