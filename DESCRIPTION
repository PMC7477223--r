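Package: neurogen
Title: Neuroadaptive Generative Modelling from Single-Trial ERP Relevance
    Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Closed-loop estimation of an operator's perceptual intention in
    the latent space of a generative model, driven by single-trial
    classification of event-related potentials (ERPs). Implements the full
    pipeline: rapid serial visual presentation (RSVP) session design with
    oddball sequencing constraints, a parametric multichannel ERP simulator
    with ground-truth relevance effects, FIR band-pass filtering, epoching,
    baseline correction, amplitude-based artifact rejection and decimation,
    spatio-temporal feature extraction, regularized linear discriminant
    analysis with Ledoit-Wolf covariance shrinkage and a confidence gate,
    Rocchio-style latent-vector intention updating with positive, negative
    and random feedback modes, and evaluation via ROC AUC, label-permutation
    significance testing and grand-average difference waves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
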