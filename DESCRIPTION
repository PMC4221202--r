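Package: snoutmorph
Title: Geometric Morphometrics of Ruminant Snout Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semilandmark outline analysis of two-dimensional snout
    (premaxilla) profiles. Provides equal arc-length outline resampling,
    generalized Procrustes superimposition, covariance-based and
    phylogenetic principal components analysis, two-group canonical
    variates analysis with a log-likelihood-ratio statistic tested
    against Monte Carlo and bootstrap null distributions,
    nearest-centroid classification with jackknifed cross-validation,
    projection of specimens of unknown ecology, back-projected shape
    models along ordination axes, and phylogenetic-comparative tools
    (Blomberg's K, Pagel's lambda, independent contrasts). A synthetic
    study generator produces two-guild outline populations, body-mass
    covariates and Brownian-motion traits on simulated trees so the
    whole pipeline can be exercised without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    picante,
    MASS,
    xml2,
    jsonlite,
    withr
Config/testthat/edition: 3
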