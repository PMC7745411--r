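Package: cellrate
Title: Time-Dependent Growth Rate Inference for Suspension Cell Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers a time-varying per-capita growth rate in suspension cell
    cultures from sparse, noisy cell counts. The population follows a logistic
    model whose growth rate is a piecewise-linear function of time; the forward
    model combines an exact deterministic solver (or a stochastic logistic
    branching-process simulator) with a two-stage observation model for
    haemocytometer counting (nested Poisson sampling plus optional miscounting
    noise). The forward model is inverted by approximate Bayesian computation
    with sequential Monte Carlo (ABC-SMC), including model comparison across
    one, two or three rate control points, and results are reported as highest
    posterior density intervals, fit tables and diagnostic figures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ggplot2,
    patchwork
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
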