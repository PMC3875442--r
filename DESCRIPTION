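Package: sigmoidGRN
Title: Gene Regulatory Network Inference with the Vohradsky Sigmoid ODE
    Model
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers gene regulatory networks from time-series expression
    data under the Vohradsky recurrent-neural-network ODE model, in which
    each gene's synthesis rate is a sigmoid function of a weighted sum of
    regulator expression levels.  The inference is decomposed gene by
    gene: for each gene a two-dimensional evolutionary search (REX/JGG)
    over the synthesis and degradation rate constants wraps a sparse
    L1-penalized linear program that estimates the regulatory weights
    from logit-linearized equations.  Includes the model simulator, a
    local-linear-regression smoother for derivative estimation, a
    least-squares comparison estimator, a synthetic benchmark generator
    with power-law in-degrees, and structure-recovery evaluation metrics
    (recall, precision, specificity, precision-recall curves).
License: Artistic-2.0
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
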