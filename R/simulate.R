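#' Configuration of the sparse regulatory expression simulator
#'
#' Expression of n genes is governed by m transcription-factor levels z
#' through a weighted bipartite graph: gene i has
#' \deqn{x_i = \mathrm{ReLU}\Big(\sum_j a_{ij} w_{ij} z_j + \epsilon_i\Big),}
#' with a binary adjacency matrix A (which regulators bind near which genes),
#' signed regulation strengths W, gamma-distributed regulator levels, and
#' optional Gaussian noise applied before rectification. Regulation is direct
#' and regulators act independently; expression is non-negative.
#'
#' The gamma parameters and the uniform weight range are implementation
#' defaults (shape 2, scale 1: positive, right-skewed, mean 2; weights
#' uniform on \[-1, 1)); both are exposed here. The default noise sd is 0.2;
#' the headline zero-noise experiment sets `noise_sd = 0`.
#'
#' @param n_genes Number of genes n (default 1000).
#' @param n_regulators Number of regulators m (default 100, must be < n).
#' @param connectivity Fraction of nonzero entries in A, in (0, 1\]
#'   (default 0.1, i.e. 90% of A is zero).
#' @param weight_low,weight_high Bounds of the uniform regulation weights.
#' @param gamma_shape,gamma_scale Gamma parameters for regulator levels.
#' @param noise_sd Standard deviation of the pre-rectification Gaussian noise.
#' @param seed Integer seed controlling every random draw.
#' @return An object of class `"regnet_config"`.
#' @export
regnet_config <- function(n_genes = 1000L, n_regulators = 100L,
                          connectivity = 0.1, weight_low = -1, weight_high = 1,
                          gamma_shape = 2, gamma_scale = 1, noise_sd = 0.2,
                          seed = 1L) {
  chk <- function(ok, field, msg)
    if (!ok) stop(sprintf("invalid '%s': %s", field, msg))
  chk(is.numeric(n_genes) && length(n_genes) == 1L && n_genes >= 1,
      "n_genes", "must be a positive integer")
  chk(is.numeric(n_regulators) && length(n_regulators) == 1L && n_regulators >= 1,
      "n_regulators", "must be a positive integer")
  chk(n_genes > n_regulators, "n_regulators", "must be smaller than n_genes")
  chk(is.numeric(connectivity) && length(connectivity) == 1L &&
        connectivity > 0 && connectivity <= 1,
      "connectivity", "must be in (0, 1]")
  chk(is.numeric(weight_low) && is.numeric(weight_high) &&
        weight_low < weight_high, "weight_low", "must be below weight_high")
  chk(is.numeric(gamma_shape) && gamma_shape > 0, "gamma_shape", "must be > 0")
  chk(is.numeric(gamma_scale) && gamma_scale > 0, "gamma_scale", "must be > 0")
  chk(is.numeric(noise_sd) && length(noise_sd) == 1L && noise_sd >= 0,
      "noise_sd", "must be >= 0")
  chk(is.numeric(seed) && length(seed) == 1L && !is.na(seed), "seed",
      "must be an integer")
  structure(list(n_genes = as.integer(n_genes),
                 n_regulators = as.integer(n_regulators),
                 connectivity = connectivity, weight_low = weight_low,
                 weight_high = weight_high, gamma_shape = gamma_shape,
                 gamma_scale = gamma_scale, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "regnet_config")
}

#' Draw a sparse bipartite regulatory network
#'
#' The adjacency matrix receives exactly `round(connectivity * n * m)` ones,
#' placed by a seeded uniform draw of positions, so the sparsity fraction is
#' exact rather than a Bernoulli average. Weights are drawn independently and
#' uniformly on \[`weight_low`, `weight_high`) for every entry; entries whose
#' adjacency is zero are ignored by the simulator.
#'
#' @param config A [regnet_config()].
#' @return An object of class `"regulatory_network"`: a list with binary
#'   `adjacency` and real `weights`, both (n_genes x n_regulators), and the
#'   `config`.
#' @export
make_network <- function(config) {
  if (!inherits(config, "regnet_config")) stop("'config' must be a regnet_config")
  n <- config$n_genes; m <- config$n_regulators
  set.seed(config$seed)
  k <- round(config$connectivity * n * m)
  A <- matrix(0, n, m)
  A[sample.int(n * m, k)] <- 1
  W <- matrix(stats::runif(n * m, config$weight_low, config$weight_high), n, m)
  structure(list(adjacency = A, weights = W, config = config),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  n <- nrow(x$adjacency); m <- ncol(x$adjacency)
  cat(sprintf("Regulatory network: %d genes x %d regulators, %d edges (%.1f%% of zeros)\n",
              n, m, sum(x$adjacency), 100 * mean(x$adjacency == 0)))
  invisible(x)
}

#' Sample regulator (transcription-factor) level vectors
#'
#' @param N Number of samples (rows), at least 1.
#' @param config A [regnet_config()] supplying the gamma parameters.
#' @param seed Seed for this draw; defaults to the config seed.
#' @return An (N x n_regulators) non-negative matrix of regulator levels.
#' @export
sample_regulators <- function(N, config, seed = config$seed) {
  if (!is.numeric(N) || length(N) != 1L || N < 1) stop("'N' must be >= 1")
  if (!inherits(config, "regnet_config")) stop("'config' must be a regnet_config")
  set.seed(seed)
  matrix(stats::rgamma(N * config$n_regulators, shape = config$gamma_shape,
                       scale = config$gamma_scale),
         as.integer(N), config$n_regulators)
}

#' Simulate expression from a network and regulator levels
#'
#' Computes `max(0, z %*% t(A * W) + noise)` row by row: per sample and gene,
#' the rectified sum of regulator contributions plus fresh Gaussian noise
#' (drawn before rectification). With `noise_sd = 0` the output is a
#' deterministic function of the network and the regulator levels.
#'
#' @param network A [make_network()] result.
#' @param z Regulator-level matrix (N x n_regulators).
#' @param noise_sd Noise standard deviation; defaults to the network config's.
#' @param seed Seed for the noise draw.
#' @return An (N x n_genes) non-negative expression matrix.
#' @export
simulate_expression <- function(network, z,
                                noise_sd = network$config$noise_sd,
                                seed = network$config$seed) {
  if (!inherits(network, "regulatory_network"))
    stop("'network' must be a regulatory_network")
  z <- as.matrix(z)
  m <- ncol(network$adjacency)
  if (ncol(z) != m)
    stop(sprintf("'z' has %d columns but the network has %d regulators",
                 ncol(z), m))
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("'noise_sd' must be >= 0")
  pre <- z %*% t(network$adjacency * network$weights)
  if (noise_sd > 0) {
    set.seed(seed)
    pre <- pre + matrix(stats::rnorm(length(pre), 0, noise_sd),
                        nrow(pre), ncol(pre))
  }
  pmax(pre, 0)
}

#' Simulate a full train/test regulatory dataset
#'
#' One call generating the study conditions of the load-sweep experiment: a
#' fresh network, gamma regulator levels for train and test, and the
#' corresponding expression matrices, with ground truth retained for
#' evaluation. Sub-draws use seeds derived from `seed` so the whole dataset
#' is one number to reproduce.
#'
#' @param n_train,n_test Training and test sample counts.
#' @param config A [regnet_config()].
#' @param seed Master seed (defaults to the config seed).
#' @return An object of class `"regulatory_data"`: list with `x_train`,
#'   `x_test`, `z_train`, `z_test`, `network`, `config`, `seed`.
#' @examples
#' d <- simulate_regulatory(20, 10, regnet_config(n_genes = 50, n_regulators = 5,
#'                                                noise_sd = 0, seed = 7))
#' dim(d$x_train)
#' @export
simulate_regulatory <- function(n_train, n_test = 100L, config = regnet_config(),
                                seed = config$seed) {
  config$seed <- as.integer(seed)
  network <- make_network(config)
  z_train <- sample_regulators(n_train, config, seed = seed + 1L)
  z_test <- sample_regulators(n_test, config, seed = seed + 2L)
  x_train <- simulate_expression(network, z_train, seed = seed + 3L)
  x_test <- simulate_expression(network, z_test, seed = seed + 4L)
  structure(list(x_train = x_train, x_test = x_test, z_train = z_train,
                 z_test = z_test, network = network, config = config,
                 seed = as.integer(seed)),
            class = "regulatory_data")
}

#' @export
print.regulatory_data <- function(x, ...) {
  cat(sprintf("Simulated regulatory dataset: %d train / %d test samples, %d genes, %d regulators (noise sd %.3g)\n",
              nrow(x$x_train), nrow(x$x_test), x$config$n_genes,
              x$config$n_regulators, x$config$noise_sd))
  invisible(x)
}
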