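Package: pushpull
Title: Constrained Recurrent Spiking Networks and Push-Pull Circuit Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction, simulation, and surrogate-gradient training of
    sparse, Dale's-law constrained recurrent networks of adaptive leaky
    integrate-and-fire (ALIF) units, together with the analyses used to
    detect cross-modulation ("push-pull") inhibition. Includes a synthetic
    motion-entropy change-detection task with a calibrated 16-channel
    Poisson input model, dual task/rate loss backpropagation-through-time
    with a spike pseudo-derivative and DEEP R sparsity-preserving rewiring,
    modulation-based weight-ratio analyses, and spike-time jitter
    perturbation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
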