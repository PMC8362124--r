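Package: cdjsdm
Title: Context-Dependent Joint Species Distribution Models Along Stress
    Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Bayesian probit joint species distribution models whose
    residual species associations vary along an environmental gradient,
    here the growing-season climatic water deficit (CWD). Latent-factor
    loadings are modelled as linear functions of the gradient, so the
    residual correlation between any two species is itself a function of
    CWD. The package provides a Gibbs sampler with probit data
    augmentation and multiplicative-gamma shrinkage priors, convergence
    diagnostics, classification of pairwise association shifts between
    wet and dry anchor points, community-association summaries over the
    gradient, contrasts against a static (context-independent) model, a
    Thornthwaite-type water-balance module deriving CWD from monthly
    climate, and a synthetic-community generator with known ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
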