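Package: bymrisk
Title: Small-Area Disease Risk Mapping with Besag-York-Mollie Spatial Models
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for small-area analysis of disease risk on areal lattices:
    contiguity-based spatial weights and Moran's I, population-proportional
    allocation of health-facility consultation counts to census areas,
    inverse-distance-weighted interpolation of pollutant monitoring stations,
    Bayesian Poisson regression with Besag-York-Mollie (convolution) random
    effects fitted by Markov chain Monte Carlo, deviance information criterion
    model comparison, and mapping of relative risks, exceedance probabilities
    and high-high/low-low risk clusters. Includes a synthetic-city simulator
    with known ground truth so every pipeline stage can be validated without
    confidential health-department data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
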