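Package: stopdcm
Title: Dynamic Causal Modelling of the Response Inhibition Network with
    Stop-Signal Behaviour
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Effective-connectivity analysis of the cortico-subcortical
    response inhibition network (preSMA, inferior frontal gyrus,
    subthalamic nucleus, primary motor cortex). Implements a bilinear and
    non-linear (activity-gated) neural state equation observed through the
    haemodynamic balloon model, variational-Laplace model inversion with a
    free-energy approximation to the log model evidence, fixed- and
    random-effects Bayesian model selection with protected exceedance
    probabilities and the Bayesian omnibus risk, Bayesian model and
    parameter averaging, a stop-signal task engine with staircase tracking
    and integration-method SSRT estimation, individual-differences
    regressions of drug-induced connectivity change, and a synthetic
    crossover-cohort generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    withr,
    Matrix,
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
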