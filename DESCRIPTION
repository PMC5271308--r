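Package: knoxclust
Title: Space-Time Clustering of Childhood Leukemia with Population-Shift-Adjusted Monte Carlo Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Knox tests of space-time interaction for point-referenced disease
    registry data over a grid of spatial and temporal lags, with a Monte Carlo
    null that resamples case locations from a time-varying child population so
    that uneven regional population shifts cannot mimic clustering. Includes
    max-statistic (min-p) adjustment for the search over lag combinations,
    graph-based linking of clustered cases into local clusters with Monte
    Carlo tests of the cluster-size spectrum, a per-case child-population
    density index (the log odds of being clustered by chance alone), and
    clustered versus nonclustered case comparisons via logistic regression
    with likelihood-ratio, Monte Carlo and Holm-corrected inference. A
    synthetic registry generator simulates inhomogeneous shifting child
    populations, birth-location case sampling, localized space-time
    mini-epidemics with covariate enrichment, and sibling pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
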