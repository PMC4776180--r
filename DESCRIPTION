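Package: catpop
Title: Recurrent Probabilistic Population Codes for Categorical Perception
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a recurrent neural-population model of categorical
    perception on the hue circle, in which a bank of von Mises-tuned
    hue-selective units interacts with winner-take-all category-selective
    units to approximate online Bayesian filtering of a hierarchical hidden
    Markov model (a slowly switching colour category emitting noisy hue
    observations).  Provides an exact grid-filtering oracle for the
    generative model, a Fisher-information ideal-observer analysis of hue
    discriminability, experiment drivers for four signatures of categorical
    processing (task-dependent gain modulation, clustering of population
    representations, drift of memorised hues toward focal colours, and a
    category-dependent discrimination threshold), and an analysis pipeline
    for multi-task neural recordings (preferred-stimulus grouping,
    fixation-normalisation, Gaussian population-profile fits, peak-shift
    dynamics with neuron-level bootstrap) together with a synthetic
    recording generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
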