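Package: redconn
Title: Redundancy Analysis of Dynamic Functional Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes a global redundancy index (RI) from parcellated BOLD
    time series via sliding-window functional connectomes: per-window
    Fisher-z correlation matrices are binarized by proportional density
    thresholding, each window's minimally connected network is tested for
    two-connectedness (biconnectivity), and RI is the fraction of windows
    whose minimally connected network is two-connected. Also provides the
    cohort-level statistical layer used to relate RI to clinical and
    lifestyle variables: standardized linear regression with covariate
    sets, Benjamini-Hochberg FDR control within cognitive domains,
    forward-backward stepwise selection with k-fold cross-validation and
    VIF screening, and percentile-bootstrap simple mediation. Includes
    synthetic-data generators (block-covariance multivariate time series
    and cohort tables with known regression and mediation ground truth) so
    the whole pipeline is testable without participant data.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    yaml,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
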