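Package: avitrend
Title: Long-Term Bird Population Trends from Heterogeneous Point-Count Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating long-term breeding-bird population trends from
    multi-project point-count surveys affected by environmental bias,
    overdispersion and zero-inflation. Counts of individuals are converted to
    breeding pairs via species conversion factors, rare species are filtered by
    relative frequency, and per-species abundance is modelled with four
    candidate count regressions (Poisson, negative binomial, zero-inflated
    Poisson and zero-inflated negative binomial) on fixed-degree-of-freedom
    spline bases for land-cover, topographic and spatial covariates, with the
    best model selected by AIC. Yearly population indices with percentile
    confidence intervals are obtained by parametric bootstrap at standardized
    covariates (restricted to the species' minimum convex hull where its range
    is localized), long-term trends are tested by confidence-interval-weighted
    least squares, and trait-based functional groups are compared through
    weighted year-by-group interaction models with finite-sample F tests. A
    synthetic-data generator with known ground truth supports end-to-end
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    grDevices,
    utils,
    MASS,
    mgcv,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
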