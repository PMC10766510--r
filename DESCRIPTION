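Package: aptvae
Title: Variational Autoencoder with a Profile HMM Decoder for Aptamer Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generative analysis of HT-SELEX aptamer libraries with a
    variational autoencoder whose decoder is a profile hidden Markov model,
    making the learned two-dimensional latent space organize sequences by
    motif content while tolerating substitutions, insertions and deletions.
    Provides the profile HMM as a standalone probabilistic object (forward
    likelihood, most probable path, most-probable-sequence reconstitution),
    a convolutional encoder and three decoder families (profile HMM,
    multicategorical, autoregressive) trained by ELBO with KL annealing and
    a Dirichlet transition regularizer, simulation-data generators with
    ground-truth motif labels, SELEX read filtering and round selection by
    unique ratio, Gaussian-mixture candidate selection with reconstitution,
    decoder truncation for shortened aptamers, and batch Bayesian
    optimization over measured binding activities via a Gaussian process
    with local penalization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
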