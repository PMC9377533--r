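Package: strokenet
Title: Longitudinal Graph Analysis of Functional Brain Networks After Stroke
Version: 0.1.0
Authors@R: person("BRAINN", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds binary functional-connectivity graphs from regional BOLD
    time series (pre-whitening, Pearson correlation, proportional
    thresholding), computes node-level graph metrics (degree, clustering
    coefficient, characteristic path length, betweenness centrality),
    quantifies their relative longitudinal change between two scanning
    sessions, attributes node-level changes to anatomical regions by
    nearest-coordinate lookup, and correlates region-averaged betweenness
    changes with upper-extremity Fugl-Meyer motor recovery. Ships a synthetic
    two-session cohort generator with modular spatial covariance, AR(1)
    temporal structure, and a plantable hub-centrality shift coupled to
    simulated motor recovery, so the whole pipeline is testable without
    external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
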