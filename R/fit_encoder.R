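#' Train an encoder against a frozen pre-trained decoder
#'
#' The decoder's weights stay fixed while the encoder learns to map inputs to
#' representations, minimizing the composed reconstruction loss
#' L(x, g_w(f(x))) against the clean data. With `noise_sd > 0` this is the
#' denoising variant: fresh Gaussian noise is added to the encoder's input
#' every epoch (one draw per sample per epoch) while the target stays clean,
#' which trains the encoder to project noisy points onto the manifold the
#' decoder already learned. With `target = "representation"` the encoder
#' instead regresses directly onto the decoder's stored training
#' representations — the two framings are equivalent up to optimization when
#' the decoder is well trained.
#'
#' @param x Training matrix (the same data the decoder was trained on).
#' @param decoder A trained [fit_decoder()] object; its weights are never
#'   updated (and are returned bitwise identical).
#' @param spec An [encoder_spec()]; defaults to a single dense
#'   leaky-rectifier layer n -> m.
#' @param control A [train_control()]; defaults to the regulatory-experiment
#'   encoder settings (Adam, learning rate 1e-4, 500 epochs).
#' @param noise_sd Input-noise standard deviation (0 = plain variant).
#' @param target `"reconstruction"` (composed loss, default) or
#'   `"representation"` (regress onto `decoder$representations`).
#' @return An object of class `"encoder_fit"`: trained encoder `layers`, the
#'   frozen `decoder`, `loss_history`, `control`, `noise_sd`, `target`.
#' @export
fit_encoder <- function(x, decoder, spec = NULL,
                        control = train_control(lr_weights = 1e-4),
                        noise_sd = 0, target = c("reconstruction", "representation")) {
  target <- match.arg(target)
  if (!inherits(decoder, "decoder_fit")) stop("'decoder' must be a decoder_fit")
  x <- check_data_matrix(x, decoder$spec$loss)
  n <- decoder$spec$out_dim; m <- decoder$spec$in_dim
  if (ncol(x) != n)
    stop(sprintf("data dimension (%d) does not match decoder output dimension (%d)",
                 ncol(x), n))
  if (is.null(spec)) spec <- encoder_spec(n_in = n, m_out = m)
  if (!inherits(spec, "encoder_spec")) stop("'spec' must be an encoder_spec")
  if (spec$out_dim != m)
    stop("encoder output dimension must equal the decoder representation dimension")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("'noise_sd' must be >= 0")
  z_target <- NULL
  if (target == "representation") {
    if (is.null(decoder$representations))
      stop("target = \"representation\" requires a decoder trained with fit_decoder()")
    if (nrow(decoder$representations) != nrow(x))
      stop("target = \"representation\" requires one decoder representation per row of 'x'")
    z_target <- decoder$representations
  }
  set.seed(control$seed)
  enc_layers <- init_layers(spec)
  res <- cpp_train_composed(x, enc_layers, decoder$layers, control$lr_weights,
                            control$weight_decay, control$batch_size,
                            control$epochs, noise_sd, TRUE,
                            .loss_codes[[decoder$spec$loss]], z_target)
  trained <- mapply(function(l, W) { l$W <- W; l }, enc_layers, res$enc_layers,
                    SIMPLIFY = FALSE)
  structure(list(layers = trained, decoder = decoder,
                 loss_history = as.numeric(res$loss_history),
                 spec = spec, control = control, noise_sd = noise_sd,
                 target = target, call = match.call()),
            class = "encoder_fit")
}

#' Train a naive autoencoder baseline
#'
#' Encoder and decoder are trained end to end from scratch on the
#' reconstruction loss, with no free representation table: representations
#' are whatever the encoder outputs. This is the comparison baseline for the
#' encoder-free decoder — the encoder's constraints generally prevent it from
#' finding the decoder-optimal representations, especially at low load.
#'
#' @param x Training matrix (N x n).
#' @param encoder_spec An [encoder_spec()] (n -> m).
#' @param decoder_spec A [decoder_spec()] (m -> n).
#' @param control A [train_control()]; defaults to the regulatory-experiment
#'   autoencoder settings (Adam, learning rate 1e-4, 1000 epochs).
#' @return An object of class `"autoencoder_fit"` with trained `enc_layers`,
#'   `dec_layers`, `loss_history` and the specs.
#' @export
fit_autoencoder <- function(x, encoder_spec, decoder_spec,
                            control = train_control(lr_weights = 1e-4,
                                                    epochs = 1000L)) {
  if (!inherits(encoder_spec, "encoder_spec"))
    stop("'encoder_spec' must be an encoder_spec")
  if (!inherits(decoder_spec, "decoder_spec"))
    stop("'decoder_spec' must be a decoder_spec")
  if (encoder_spec$out_dim != decoder_spec$in_dim)
    stop("encoder output and decoder input dimensions must match")
  x <- check_data_matrix(x, decoder_spec$loss)
  if (ncol(x) != decoder_spec$out_dim || encoder_spec$in_dim != ncol(x))
    stop("data dimension must match encoder input and decoder output")
  set.seed(control$seed)
  enc_layers <- init_layers(encoder_spec)
  dec_layers <- init_layers(decoder_spec)
  res <- cpp_train_composed(x, enc_layers, dec_layers, control$lr_weights,
                            control$weight_decay, control$batch_size,
                            control$epochs, 0, FALSE,
                            .loss_codes[[decoder_spec$loss]], NULL)
  enc <- mapply(function(l, W) { l$W <- W; l }, enc_layers, res$enc_layers,
                SIMPLIFY = FALSE)
  dec <- mapply(function(l, W) { l$W <- W; l }, dec_layers, res$dec_layers,
                SIMPLIFY = FALSE)
  structure(list(enc_layers = enc, dec_layers = dec,
                 loss_history = as.numeric(res$loss_history),
                 encoder_spec = encoder_spec, decoder_spec = decoder_spec,
                 control = control, call = match.call()),
            class = "autoencoder_fit")
}

#' @param object An `"encoder_fit"`.
#' @param newdata New data matrix.
#' @param type `"representation"` (encoder output) or `"reconstruction"`
#'   (through the frozen decoder).
#' @rdname fit_encoder
#' @export
predict.encoder_fit <- function(object, newdata,
                                type = c("representation", "reconstruction"),
                                ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  z <- forward_layers(object$layers, x)
  if (type == "representation") z else reconstruct(object$decoder, z)
}

#' @param object An `"autoencoder_fit"`.
#' @rdname fit_autoencoder
#' @export
predict.autoencoder_fit <- function(object, newdata,
                                    type = c("representation", "reconstruction"),
                                    ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  z <- forward_layers(object$enc_layers, x)
  if (type == "representation") z else forward_layers(object$dec_layers, z)
}

#' @export
print.encoder_fit <- function(x, ...) {
  cat(sprintf("Encoder fit on frozen decoder (%s target, input noise sd %.3g)\n",
              x$target, x$noise_sd))
  cat(sprintf("  trained %d epochs; final loss %.4g\n",
              length(x$loss_history), utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' @export
print.autoencoder_fit <- function(x, ...) {
  cat("Naive autoencoder fit (end-to-end, no decoder pre-training)\n")
  cat(sprintf("  trained %d epochs; final loss %.4g\n",
              length(x$loss_history), utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' @export
coef.encoder_fit <- function(object, ...) {
  ws <- lapply(object$layers, `[[`, "W")
  names(ws) <- paste0("layer", seq_along(ws))
  ws
}

#' @export
coef.autoencoder_fit <- function(object, ...) {
  list(encoder = lapply(object$enc_layers, `[[`, "W"),
       decoder = lapply(object$dec_layers, `[[`, "W"))
}

#' @export
plot.encoder_fit <- function(x, ...) {
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "l",
                 log = "y", xlab = "epoch", ylab = "mean training loss",
                 main = "Encoder training (frozen decoder)", ...)
  invisible(x)
}

#' @export
plot.autoencoder_fit <- function(x, ...) {
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "l",
                 log = "y", xlab = "epoch", ylab = "mean training loss",
                 main = "Autoencoder training", ...)
  invisible(x)
}
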