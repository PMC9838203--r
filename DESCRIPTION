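Package: tmaxblend
Title: Bayesian Integration of Station Temperature Records with Gridded Reanalysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates point-location daily maximum temperature station records
    with gridded reanalysis output through a Bayesian hierarchical model.
    Erroneous outliers are detected with a discrete Gaussian/Uniform mixture,
    station-reanalysis bias is captured by spatially varying linear terms built
    from thin-plate regression splines plus station-specific non-linear
    penalised-spline deviations, and inference uses a bespoke Gibbs sampler
    with random-walk Metropolis updates for the penalty parameters. Posterior
    predictive simulation supports imputation of missing station values,
    statistical downscaling to arbitrary grids, aggregation to polygon regions
    and decomposition of predictive uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    coda,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
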