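Package: decoderfit
Title: Encoder-Free Representation Learning by Joint Decoder and Latent Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trains neural-network decoders without an encoder by optimizing
    the decoder weights jointly with one free latent representation per
    training sample, in the manifold-learning view where the decoder defines a
    low-dimensional manifold and training minimizes the distance between the
    data and their projections onto it. Provides load (constraints-per-
    parameter) theory for decoders and encoders, encoder fitting against a
    frozen pre-trained decoder (including a denoising variant), naive
    autoencoder baselines, a sparse bipartite gene-regulatory expression
    simulator with ground-truth regulator levels, latent-recovery evaluation
    by per-dimension Pearson correlation, a principal-subspace oracle for the
    linear case, and a seeded load-sweep experiment driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
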