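Package: cwlearn
Title: Confidence-Weighted Learning of Volatile Transition Probabilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for confidence-weighted
    statistical learning of binary sequences. Generates tone sequences
    from a change-point generative process with volatile first-order
    transition probabilities, runs a Bayes-optimal hidden Markov ideal
    observer on a discretized probability grid, and derives its
    trial-by-trial latent variables: prediction, Shannon surprise,
    confidence (posterior log-precision) and Kullback-Leibler belief
    update. Includes the downstream statistical machinery used to study
    these latents: residualized confidence regressors, trial binning,
    mass-univariate regression with one-dimensional cluster-based
    permutation correction, a cross-subject shuffle control, and
    cross-validated ridge decoding, together with generators for
    synthetic single-trial neural (band power, evoked response) and
    pupillometric signals with a known coupling to the latent variables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    knitr
Config/testthat/edition: 3
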