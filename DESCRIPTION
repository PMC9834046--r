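Package: paeval
Title: Protected-Area Effectiveness Analysis for Bird Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate the association between statutory protected-area
    (PA) designations and bird population state, change, demography and
    community structure from multi-scheme citizen-science monitoring data.
    Simulates atlas presence, annual two-visit count and constant-effort
    ringing streams over a confounded landscape with known ground-truth PA
    effects; classifies two-period occupancy transitions (occurrence,
    colonization, persistence) with breeding-evidence filtering; fits
    per-species generalized additive models with a spatial-elevation tensor
    smooth and year random effects to estimate PA coefficients for occurrence,
    abundance, abundance trend and productivity; aggregates effects across
    species with sign and t tests; builds Mahalanobis-matched counterfactual
    samples with balance diagnostics; relates effects to species traits under
    Brownian phylogenetic correlation with inverse-variance weighting (GLS and
    MCMC engines); and computes community specialisation and temperature
    indices with Hill diversity.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    MASS,
    metafor,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
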