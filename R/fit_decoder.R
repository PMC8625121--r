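#' Optimizer settings for decoder, encoder and autoencoder training
#'
#' Defaults are the regulatory-experiment values: Adam on the weights with
#' learning rate `lr_weights` and L2 weight decay 1e-5, momentum gradient
#' descent on the representations with learning rate 0.01 and momentum 0.9,
#' mini-batches of 32, 500 epochs. Weight decay never touches representation
#' rows (decaying them fights the reconstruction objective). Representations
#' are initialized from a seeded Normal(0, `rep_init_sd`^2); the small scale
#' keeps rectifier units out of their dead zone at the start.
#'
#' @param lr_weights Adam learning rate for weights.
#' @param lr_reps Learning rate of the momentum SGD on representations.
#' @param momentum_reps Momentum of the representation optimizer, in \[0, 1).
#' @param weight_decay L2 penalty coefficient on weights.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs (each representation row receives one update
#'   per epoch, when its batch is visited).
#' @param seed Seed for initialization and batch shuffling.
#' @param rep_init_sd SD of the representation initialization.
#' @param infer_epochs Maximum epochs for test-time representation inference.
#' @param infer_tol,infer_patience Plateau early stopping for inference: stop
#'   after `infer_patience` consecutive epochs that fail to improve on the
#'   best loss by at least `infer_tol`. The patience default (100) exceeds
#'   the ringing period of the momentum optimizer, so transient oscillations
#'   are not mistaken for convergence.
#' @param infer_restarts Number of seeded restarts for inference; each
#'   sample keeps its best (lowest-loss) representation across restarts.
#' @param nonneg_reps Constrain representations to be non-negative (projected
#'   gradient step, half-normal initialization). The decoder's output
#'   rectifier leaves the sign of each representation dimension (jointly with
#'   its weight column) unidentifiable; when the latent quantities are known
#'   to be non-negative — regulator concentrations here — restricting the
#'   representations to their natural orthant removes that symmetry and makes
#'   the recovered dimensions sign-identifiable. Default `FALSE` for generic
#'   data.
#' @return An object of class `"train_control"`.
#' @export
train_control <- function(lr_weights = 1e-3, lr_reps = 1e-2,
                          momentum_reps = 0.9, weight_decay = 1e-5,
                          batch_size = 32L, epochs = 500L, seed = 1L,
                          rep_init_sd = 0.1, infer_epochs = 500L,
                          infer_tol = 1e-6, infer_patience = 100L,
                          infer_restarts = 1L, nonneg_reps = FALSE) {
  stopifnot(lr_weights > 0, lr_reps > 0,
            momentum_reps >= 0, momentum_reps < 1,
            weight_decay >= 0, batch_size >= 1, epochs >= 1,
            rep_init_sd > 0, infer_epochs >= 1, infer_tol >= 0,
            infer_patience >= 1, infer_restarts >= 1)
  structure(list(lr_weights = lr_weights, lr_reps = lr_reps,
                 momentum_reps = momentum_reps, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 rep_init_sd = rep_init_sd,
                 infer_epochs = as.integer(infer_epochs),
                 infer_tol = infer_tol,
                 infer_patience = as.integer(infer_patience),
                 infer_restarts = as.integer(infer_restarts),
                 nonneg_reps = isTRUE(nonneg_reps)),
            class = "train_control")
}

# Canonical sign orientation for single-layer decoders. Flipping the sign of
# representation dimension j together with weight column j leaves z %*% t(W)
# -- and hence every prediction -- unchanged, so the sign of each latent
# dimension is a free convention (as for principal-component loadings). We fix
# it so every representation column has non-negative mean, which makes
# dimensions sign-identifiable when the underlying latent quantities are
# non-negative (regulator concentrations). Multi-layer decoders have no such
# exact symmetry and are left untouched.
orient_decoder <- function(layers, Z) {
  if (length(layers) != 1L || is.null(Z)) return(list(layers = layers, Z = Z))
  flip <- colMeans(Z) < 0
  if (any(flip)) {
    Z[, flip] <- -Z[, flip]
    layers[[1L]]$W[, flip] <- -layers[[1L]]$W[, flip]
  }
  list(layers = layers, Z = Z)
}

# seeded representation start: Normal(0, sd^2), folded to the non-negative
# orthant when representations are constrained there
init_reps <- function(N, m, control) {
  z <- matrix(stats::rnorm(N * m, 0, control$rep_init_sd), N, m)
  if (control$nonneg_reps) z <- abs(z)
  z
}

check_data_matrix <- function(x, loss = "mse") {
  x <- as.matrix(x)
  if (!is.numeric(x) || nrow(x) < 1L) stop("'x' must be a numeric matrix")
  if (anyNA(x) || any(!is.finite(x))) stop("'x' contains NA/NaN/Inf values")
  if (loss == "bce" && (min(x) < 0 || max(x) > 1))
    stop("binary cross-entropy requires data in [0, 1]")
  x
}

#' Fit a decoder without an encoder
#'
#' Jointly optimizes the decoder weights and one free m-dimensional
#' representation per training sample by gradient descent, minimizing
#' \eqn{\sum_k L(x_k, g_w(z_k))}. In the manifold view this moves the
#' decoder's m-dimensional manifold to lie as close as possible to the
#' training points; the learned z are the coordinates of each sample's
#' projection. Weights get Adam steps per mini-batch; each representation row
#' gets one momentum-SGD step per epoch. The scaling/symmetry degeneracy of
#' the solution (w x = (w/s)(z s)) is tamed by the small weight decay.
#'
#' @param x Training matrix, samples in rows (N x n).
#' @param spec A [decoder_spec()] whose output dimension equals `ncol(x)`.
#' @param control A [train_control()].
#' @return An object of class `"decoder_fit"`: list with trained `layers`,
#'   the representation matrix `representations` (N x m), per-epoch
#'   `loss_history`, plus `spec`, `control` and the training data `x`.
#' @seealso [infer_representations()], [reconstruct()], [fit_encoder()],
#'   [decoder_load()]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60 * 10), 60, 10)
#' fit <- fit_decoder(x, decoder_spec(list(dense_layer(2, 10))),
#'                    train_control(epochs = 50, seed = 1))
#' plot(fit)
#' @export
fit_decoder <- function(x, spec, control = train_control()) {
  if (!inherits(spec, "decoder_spec")) stop("'spec' must be a decoder_spec")
  x <- check_data_matrix(x, spec$loss)
  if (ncol(x) != spec$out_dim)
    stop(sprintf("data dimension (%d) does not match decoder output dimension (%d)",
                 ncol(x), spec$out_dim))
  m <- spec$in_dim
  set.seed(control$seed)
  layers <- init_layers(spec)
  Z0 <- init_reps(nrow(x), m, control)
  res <- cpp_train_joint(x, layers, Z0, control$lr_weights, control$lr_reps,
                         control$momentum_reps, control$weight_decay,
                         control$batch_size, control$epochs,
                         .loss_codes[[spec$loss]], control$nonneg_reps)
  trained <- mapply(function(l, W) { l$W <- W; l }, layers, res$layers,
                    SIMPLIFY = FALSE)
  oriented <- orient_decoder(trained, res$Z)
  trained <- oriented$layers
  res$Z <- oriented$Z
  structure(list(layers = trained, representations = res$Z,
                 loss_history = as.numeric(res$loss_history),
                 spec = spec, control = control, x = x,
                 call = match.call()),
            class = "decoder_fit")
}

#' Build a decoder with known weights
#'
#' Wraps fixed weight matrices (for example the simulator's ground-truth
#' masked weights) in a `decoder_fit` object without training, so it can be
#' used with [reconstruct()], [infer_representations()] and
#' [evaluate_model()].
#'
#' @param spec A [decoder_spec()].
#' @param weights A matrix (single layer) or list of matrices, each
#'   (out_dim x in_dim).
#' @param control A [train_control()] used for later inference.
#' @return A `"decoder_fit"` with no training history or representations.
#' @export
decoder_model <- function(spec, weights, control = train_control()) {
  if (!inherits(spec, "decoder_spec")) stop("'spec' must be a decoder_spec")
  structure(list(layers = layers_with_weights(spec, weights),
                 representations = NULL, loss_history = numeric(0),
                 spec = spec, control = control, x = NULL,
                 call = match.call()),
            class = "decoder_fit")
}

#' Map representations through a decoder
#'
#' @param object A fitted decoder (or autoencoder/encoder fit; the decoder
#'   part is used).
#' @param z Representation matrix (rows are samples, `m` columns).
#' @return The (rows x n) reconstruction matrix.
#' @export
reconstruct <- function(object, z) UseMethod("reconstruct")

#' @export
reconstruct.decoder_fit <- function(object, z) {
  z <- as.matrix(z)
  if (ncol(z) != object$spec$in_dim)
    stop(sprintf("'z' has %d columns but the decoder representation dimension is %d",
                 ncol(z), object$spec$in_dim))
  forward_layers(object$layers, z)
}

#' Infer representations for new samples on a fixed decoder
#'
#' With the decoder weights frozen, each new sample's representation is found
#' by the same momentum gradient descent used in training, from a seeded
#' Normal(0, `rep_init_sd`^2) start, stopping at `infer_epochs` or when the
#' loss improves by less than `infer_tol` for `infer_patience` consecutive
#' epochs. The optimization can in principle be trapped in local minima;
#' `infer_restarts > 1` reruns from different seeds and keeps each sample's
#' best representation.
#'
#' @param object A `"decoder_fit"`.
#' @param newdata Matrix of new samples (rows), `n` columns.
#' @param control Optional [train_control()]; defaults to the fit's.
#' @return The (rows x m) representation matrix, with attributes
#'   `"per_sample_loss"` (final element-mean loss per row) and `"epochs"`
#'   (epochs used in the kept restart).
#' @export
infer_representations <- function(object, newdata, control = NULL) {
  if (!inherits(object, "decoder_fit")) stop("'object' must be a decoder_fit")
  if (is.null(control)) control <- object$control
  x <- check_data_matrix(newdata, object$spec$loss)
  if (ncol(x) != object$spec$out_dim)
    stop(sprintf("'newdata' has %d columns but the decoder output dimension is %d",
                 ncol(x), object$spec$out_dim))
  m <- object$spec$in_dim
  loss_code <- .loss_codes[[object$spec$loss]]
  best_z <- NULL; best_loss <- NULL; best_epochs <- NA_integer_
  for (r in seq_len(control$infer_restarts)) {
    set.seed(control$seed + 101L * (r - 1L))
    Z0 <- init_reps(nrow(x), m, control)
    res <- cpp_infer_reps(x, object$layers, Z0, control$lr_reps,
                          control$momentum_reps, control$infer_epochs,
                          control$infer_tol, control$infer_patience, loss_code,
                          control$nonneg_reps)
    if (is.null(best_z)) {
      best_z <- res$Z; best_loss <- as.numeric(res$per_sample_loss)
      best_epochs <- res$epochs
    } else {
      better <- as.numeric(res$per_sample_loss) < best_loss
      best_z[better, ] <- res$Z[better, , drop = FALSE]
      best_loss[better] <- res$per_sample_loss[better]
    }
  }
  structure(best_z, per_sample_loss = best_loss, epochs = best_epochs)
}

#' @export
print.decoder_fit <- function(x, ...) {
  cat("Decoder fit (encoder-free representation learning)\n")
  cat(sprintf("  architecture: %s -> %s, loss %s\n", x$spec$in_dim,
              paste(vapply(x$spec$layers, function(l) l$out_dim, integer(1)),
                    collapse = " -> "), x$spec$loss))
  if (!is.null(x$representations))
    cat(sprintf("  trained on %d samples for %d epochs; final loss %.4g\n",
                nrow(x$representations), length(x$loss_history),
                utils::tail(x$loss_history, 1)))
  else cat("  fixed weights (not trained)\n")
  invisible(x)
}

#' @export
summary.decoder_fit <- function(object, ...) {
  c_d <- model_complexity(object$layers)
  N <- if (!is.null(object$representations)) nrow(object$representations) else NA
  out <- list(fit = object, complexity = c_d,
              load = if (!is.na(N))
                load_report(N, object$spec$out_dim, object$spec$in_dim, c_d))
  class(out) <- "summary.decoder_fit"
  out
}

#' @export
print.summary.decoder_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  complexity (trainable weights): %d\n", x$complexity))
  if (!is.null(x$load)) print(x$load)
  invisible(x)
}

#' @export
coef.decoder_fit <- function(object, ...) {
  ws <- lapply(object$layers, `[[`, "W")
  names(ws) <- paste0("layer", seq_along(ws))
  ws
}

#' @export
fitted.decoder_fit <- function(object, ...) {
  if (is.null(object$representations))
    stop("decoder was built with fixed weights; no training representations")
  reconstruct(object, object$representations)
}

#' @export
residuals.decoder_fit <- function(object, ...) {
  if (is.null(object$x)) stop("no training data stored in this object")
  object$x - fitted(object)
}

#' @param newdata New data matrix (samples x n).
#' @param type `"representation"` to return inferred latent vectors,
#'   `"reconstruction"` to return their decoder images.
#' @rdname infer_representations
#' @export
predict.decoder_fit <- function(object, newdata,
                                type = c("representation", "reconstruction"),
                                control = NULL, ...) {
  type <- match.arg(type)
  z <- infer_representations(object, newdata, control)
  if (type == "representation") z else reconstruct(object, z)
}

#' @export
plot.decoder_fit <- function(x, ...) {
  if (!length(x$loss_history)) stop("no training history to plot")
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "l",
                 log = "y", xlab = "epoch", ylab = "mean training loss",
                 main = "Decoder training", ...)
  invisible(x)
}
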