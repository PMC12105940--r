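Package: synchroscope
Title: Spatial Population Synchrony: Moving-Window Estimation, Pair Covariates,
    and Permutation Inference for Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying spatial synchrony of population dynamics in
    long-term monitoring data. Converts abundance series to log growth rates,
    estimates pairwise population and seasonal-climate synchrony over 10-year
    moving windows with quality-control exclusion rules, computes pair-level
    control covariates (Euclidean distance, mean northing, Renkonen habitat
    similarity), builds species attribute tables (specialism, mobility,
    abundance change classes), and fits mixed-effects models relating synchrony
    to climate synchrony and species attributes, with permutation F tests for
    inference. Includes a dispersal-coupled metapopulation simulator with a
    spatially autocorrelated climate field (optionally with a temporal trend in
    its correlation range) so every stage can be validated against known ground
    truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    nloptr,
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
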