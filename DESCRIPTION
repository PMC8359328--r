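Package: dsrt
Title: Discretized Signed Residual Time Models for Accuracy and Response Time
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint measurement of ability and response speed from item response
    accuracy and response time under a deadline, using the discretized signed
    residual time (SRT) model family. Responses are scored by combining accuracy
    with a fast/slow split of response time; the resulting polytomous scores are
    modelled with unidimensional and two-dimensional nominal-response-type item
    response models, the latter adding a latent speed dimension with a free
    correlation to ability. Provides marginal maximum likelihood estimation via
    an EM algorithm with Gauss-Hermite quadrature, EAP person scoring with
    model-based reliability, a positive-manifold diagnostic based on the first
    eigenvalue of the inter-item response-time correlation matrix with a
    parametric-bootstrap predictive check, comparison fits of hierarchical and
    IRTree models, simulators for every model variant including the continuous
    SRT model, and a Monte Carlo study harness for bias/variance/MSE and EAP
    reliability of ability estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    parallel,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
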