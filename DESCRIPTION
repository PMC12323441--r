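Package: ggmboot
Title: Cluster-Based Bootstrap Inference for Gaussian Graphical Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns Gaussian graphical models (partial correlation
    networks) from clustered data, such as family studies, where
    observations within a cluster are correlated.  Edge tests are based
    on a cluster bootstrap estimate of the standard error of the
    standardized Fisher Z statistic, which controls the type I error
    that conventional tests inflate when within-cluster correlation is
    ignored.  Includes the conventional Fisher Z test and a naive
    individual-level bootstrap as baselines, a variance-components
    simulator of multivariate family traits with configurable
    heritability, and a simulation harness for false-positive-rate and
    power studies with an iterative significance-level adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
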