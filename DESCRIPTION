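Package: lhpulse
Title: Bayesian Inference of Pulsatile Luteinizing Hormone Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a discrete-time stochastic state-space model of pulsatile
    luteinizing hormone (LH) secretion and clearance to serial serum LH
    measurements. The latent hypothalamic drive combines a two-state (on/off)
    telegraph process with a bounded basal signal; observations carry
    multiplicative assay noise. Inference is by particle Gibbs: conditional
    sequential Monte Carlo with ancestor sampling for the latent path,
    adaptive Metropolis-Hastings for the switch timescales, and a simplified
    manifold MALA step for secretion, clearance and pulsatility-strength
    parameters. Includes posterior pulse-probability traces with threshold
    pulse calling, a composite pre/post-intervention model with shared
    clearance, an exact grid-filter oracle for validation, a synthetic-profile
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
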