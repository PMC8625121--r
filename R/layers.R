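#' @useDynLib decoderfit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.act_codes <- c(linear = 0L, relu = 1L, leaky_relu = 2L, sigmoid = 3L)
.loss_codes <- c(mse = 0L, bce = 1L)

#' Dense linear layer
#'
#' A fully connected linear map with an optional elementwise activation and no
#' bias term (parameter counts then equal weight counts, and the regulatory
#' decoder of [simulate_regulatory()] has no additive constant either).
#'
#' @param in_dim,out_dim Positive integers, input and output dimension.
#' @param activation One of `"linear"`, `"relu"`, `"leaky_relu"`, `"sigmoid"`.
#' @param slope Negative-side slope of the leaky rectifier (default 0.1).
#' @return A layer description used by [decoder_spec()] / [encoder_spec()].
#' @export
dense_layer <- function(in_dim, out_dim,
                        activation = c("linear", "relu", "leaky_relu", "sigmoid"),
                        slope = 0.1) {
  activation <- match.arg(activation)
  if (!is.numeric(in_dim) || length(in_dim) != 1L || in_dim < 1)
    stop("'in_dim' must be a positive integer")
  if (!is.numeric(out_dim) || length(out_dim) != 1L || out_dim < 1)
    stop("'out_dim' must be a positive integer")
  structure(list(kind = "dense", in_dim = as.integer(in_dim),
                 out_dim = as.integer(out_dim), mask = NULL,
                 activation = activation, slope = slope),
            class = "net_layer")
}

#' Sparse (masked) linear layer
#'
#' A linear layer whose weight matrix is constrained to a fixed binary support:
#' entries where `mask` is zero are structurally zero and never trained. Used
#' for the regulatory decoder, whose support is the gene-by-regulator
#' adjacency matrix, making each latent unit identifiable as one regulator.
#'
#' @param mask Binary matrix of shape (out_dim x in_dim); for the regulatory
#'   decoder this is the adjacency matrix (genes x regulators).
#' @inheritParams dense_layer
#' @return A layer description used by [decoder_spec()] / [encoder_spec()].
#' @export
sparse_layer <- function(mask,
                         activation = c("linear", "relu", "leaky_relu", "sigmoid"),
                         slope = 0.1) {
  activation <- match.arg(activation)
  mask <- as.matrix(mask)
  if (!all(mask %in% c(0, 1))) stop("'mask' must be binary")
  structure(list(kind = "sparse", in_dim = ncol(mask), out_dim = nrow(mask),
                 mask = mask, activation = activation, slope = slope),
            class = "net_layer")
}

check_chain <- function(layers, what) {
  if (length(layers) < 1L) stop("'layers' must contain at least one layer")
  for (l in layers)
    if (!inherits(l, "net_layer"))
      stop("all elements of 'layers' must be created by dense_layer()/sparse_layer()")
  for (i in seq_along(layers)[-1L])
    if (layers[[i]]$in_dim != layers[[i - 1L]]$out_dim)
      stop(sprintf("%s layer %d input dim (%d) does not match layer %d output dim (%d)",
                   what, i, layers[[i]]$in_dim, i - 1L, layers[[i - 1L]]$out_dim))
  invisible(layers)
}

#' Decoder architecture specification
#'
#' Describes the map \eqn{g_w} from an m-dimensional representation space to
#' n-dimensional input space. Its image is an (at most) m-dimensional manifold
#' in input space; fitting the decoder means moving that manifold as close to
#' the training data as the loss allows.
#'
#' @param layers List of layers from [dense_layer()] / [sparse_layer()],
#'   chaining from the representation dimension m to the data dimension n.
#' @param loss `"mse"` (squared error) or `"bce"` (binary cross-entropy;
#'   requires a final sigmoid activation and data in \[0, 1\]).
#' @return An object of class `"decoder_spec"`.
#' @examples
#' spec <- decoder_spec(list(dense_layer(5, 50)), loss = "mse")
#' @export
decoder_spec <- function(layers, loss = c("mse", "bce")) {
  loss <- match.arg(loss)
  check_chain(layers, "decoder")
  last <- layers[[length(layers)]]
  if (loss == "bce" && last$activation != "sigmoid")
    stop("binary cross-entropy requires a final sigmoid activation")
  structure(list(layers = layers, loss = loss,
                 in_dim = layers[[1L]]$in_dim, out_dim = last$out_dim),
            class = "decoder_spec")
}

#' Encoder architecture specification
#'
#' Describes the map from n-dimensional input space to the m-dimensional
#' representation space. The default matches the regulatory experiment: a
#' single dense linear layer with leaky-rectifier activation (slope 0.1).
#'
#' @param layers List of layers chaining from n to m. If `NULL`, a single
#'   dense leaky-rectifier layer `n_in` -> `m_out` is used.
#' @param n_in,m_out Dimensions used for the default single-layer encoder.
#' @return An object of class `"encoder_spec"`.
#' @export
encoder_spec <- function(layers = NULL, n_in = NULL, m_out = NULL) {
  if (is.null(layers)) {
    if (is.null(n_in) || is.null(m_out))
      stop("either 'layers' or both 'n_in' and 'm_out' must be given")
    layers <- list(dense_layer(n_in, m_out, activation = "leaky_relu", slope = 0.1))
  }
  check_chain(layers, "encoder")
  structure(list(layers = layers,
                 in_dim = layers[[1L]]$in_dim,
                 out_dim = layers[[length(layers)]]$out_dim),
            class = "encoder_spec")
}

# Seeded weight initialization: uniform(-1/sqrt(fan_in), 1/sqrt(fan_in)),
# masked entries zeroed. Returns the list-of-layers structure the C++ core
# consumes: list(W, mask, act, slope).
init_layers <- function(spec) {
  lapply(spec$layers, function(l) {
    bound <- 1 / sqrt(l$in_dim)
    W <- matrix(stats::runif(l$out_dim * l$in_dim, -bound, bound),
                l$out_dim, l$in_dim)
    if (!is.null(l$mask)) W <- W * l$mask
    list(W = W, mask = l$mask, act = .act_codes[[l$activation]],
         slope = l$slope)
  })
}

# Wrap already-known weights (e.g. the simulator's ground truth) in the same
# structure.
layers_with_weights <- function(spec, weights) {
  if (!is.list(weights)) weights <- list(weights)
  if (length(weights) != length(spec$layers))
    stop("'weights' must supply one matrix per layer")
  mapply(function(l, W) {
    W <- as.matrix(W)
    if (!all(dim(W) == c(l$out_dim, l$in_dim)))
      stop("weight matrix dimensions do not match the layer specification")
    if (!is.null(l$mask)) W <- W * l$mask
    list(W = W, mask = l$mask, act = .act_codes[[l$activation]], slope = l$slope)
  }, spec$layers, weights, SIMPLIFY = FALSE)
}

forward_layers <- function(layers, input) {
  cpp_forward(layers, as.matrix(input))$output
}
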