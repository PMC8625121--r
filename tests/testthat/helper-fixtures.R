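# Small study-condition presets used across tests. The full experiment uses
# n = 1000 genes and m = 100 regulators; unit tests use a reduced geometry
# with the same structure (sparse bipartite network, gamma regulators,
# rectified linear readout) so each test runs in seconds.

tiny_config <- function(seed = 1L, noise_sd = 0, n_genes = 60L,
                        n_regulators = 6L, connectivity = 0.2) {
  regnet_config(n_genes = n_genes, n_regulators = n_regulators,
                connectivity = connectivity, noise_sd = noise_sd, seed = seed)
}

tiny_data <- function(n_train = 40L, n_test = 20L, seed = 1L, ...) {
  simulate_regulatory(n_train, n_test, tiny_config(seed = seed, ...),
                      seed = seed)
}

tiny_decoder_spec <- function(data, activation = "relu") {
  decoder_spec(list(sparse_layer(data$network$adjacency, activation)))
}
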