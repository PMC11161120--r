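Package: hocoord
Title: Dynamic Inference of Higher-Order Spiking Coordination in Neuronal Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models binned ensemble spike trains as a discretized marked point
    process in which every non-empty simultaneous-spiking pattern of C neurons
    is one of 2^C - 1 disjoint marks, fit as a multinomial logistic GLM with
    optional ensemble spiking-history covariates. Parameters are tracked over
    time by sequential maximum likelihood with a forgetting factor, using an
    adaptive greedy (orthogonal matching pursuit) scheme for sparse history
    couplings, with de-sparsified estimates and confidence intervals.
    Significant rth-order coordination is detected per window by an adaptive
    de-biased deviance difference test with chi-square and non-central
    chi-square limits, summarized by a signed Youden J-statistic after
    state-space smoothing of the non-centrality parameter. Includes a
    ground-truth simulator for non-stationary ensemble spiking, single-trial
    baseline synchrony measures, and delimited-text readers and writers for
    binned spike data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
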