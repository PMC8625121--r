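#' Model complexity: the count of trainable weight entries
#'
#' The effective number of parameters of a network has no exact theory; the
#' number of multiplicative weight entries is an upper bound and is used as
#' the complexity throughout. Masked (structurally zero) entries are never
#' trainable and are not counted; biases are absent from these architectures.
#'
#' @param x A `decoder_spec`, `encoder_spec`, a list of layers, or a fitted
#'   model object.
#' @return Non-negative integer count of trainable weights.
#' @examples
#' model_complexity(decoder_spec(list(dense_layer(100, 1000))))  # 100000
#' @export
model_complexity <- function(x) UseMethod("model_complexity")

#' @export
model_complexity.decoder_spec <- function(x) model_complexity(x$layers)

#' @export
model_complexity.encoder_spec <- function(x) model_complexity(x$layers)

#' @export
model_complexity.list <- function(x) {
  if (length(x) == 0L) return(0L)
  counts <- vapply(x, function(l) {
    if (inherits(l, "net_layer")) {
      if (is.null(l$mask)) l$in_dim * l$out_dim else sum(l$mask != 0)
    } else if (is.list(l) && !is.null(l$W)) {  # internal trained-layer form
      if (is.null(l$mask)) length(l$W) else sum(l$mask != 0)
    } else stop("cannot count complexity of this layer description")
  }, numeric(1))
  as.integer(sum(counts))
}

check_pos_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1)
    stop(sprintf("'%s' must be a positive integer", name))
  invisible(x)
}

#' Decoder load
#'
#' The load of a decoder trained jointly with free per-sample representations
#' is the number of data constraints per trainable parameter,
#' \deqn{\alpha_d = \frac{Nn}{C_d + Nm},}
#' where N is the number of training samples, n the input dimension, m the
#' representation dimension and \eqn{C_d} the decoder complexity. A load above
#' 1 means the system is over-determined (the manifold cannot interpolate the
#' data exactly and must average over noise); below 1 it is under-determined.
#' As N grows the load increases towards the compression rate n/m.
#'
#' @param N Number of training samples.
#' @param n Input (data) dimension.
#' @param m Representation dimension.
#' @param c_d Decoder complexity (weight count), e.g. [model_complexity()].
#' @return The decoder load, a positive real.
#' @examples
#' decoder_load(10000, 1000, 100, 10000)  # ~9.9
#' @export
decoder_load <- function(N, n, m, c_d) {
  check_pos_int(N, "N"); check_pos_int(n, "n"); check_pos_int(m, "m")
  if (!is.numeric(c_d) || length(c_d) != 1L || is.na(c_d) || c_d < 0)
    stop("'c_d' must be a non-negative number")
  (N * n) / (c_d + N * m)
}

#' Encoder load
#'
#' With the training representations fixed (as when an encoder is trained
#' against a frozen pre-trained decoder), the encoder faces mN constraints on
#' \eqn{C_e} weights, so \deqn{\alpha_e = \frac{mN}{C_e}.}
#'
#' @param N Number of training samples (0 allowed, giving load 0).
#' @param m Representation dimension.
#' @param c_e Encoder complexity (weight count), must be positive.
#' @return The encoder load, a non-negative real.
#' @export
encoder_load <- function(N, m, c_e) {
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 0)
    stop("'N' must be a non-negative integer")
  check_pos_int(m, "m")
  if (!is.numeric(c_e) || length(c_e) != 1L || is.na(c_e) || c_e <= 0)
    stop("encoder load is undefined for complexity 'c_e' = 0")
  (m * N) / c_e
}

#' Relation between encoder and decoder load at equal complexity
#'
#' When encoder and decoder have the same complexity \eqn{C_e = C_d} and
#' m < n, \deqn{\alpha_d = \frac{n}{m}\,\frac{\alpha_e}{1 + \alpha_e}.}
#' For small \eqn{\alpha_e} the decoder load is n/m times larger; for large
#' \eqn{\alpha_e} it saturates at the compression rate n/m. The decoder is
#' therefore generally far better specified by the same data than the encoder.
#'
#' @param alpha_e Encoder load, non-negative (may be `Inf`).
#' @param n Input dimension.
#' @param m Representation dimension.
#' @return The implied decoder load.
#' @examples
#' load_relation(1, 1000, 100)  # 5
#' @export
load_relation <- function(alpha_e, n, m) {
  if (!is.numeric(alpha_e) || length(alpha_e) != 1L || is.na(alpha_e) || alpha_e < 0)
    stop("'alpha_e' must be a non-negative number")
  check_pos_int(n, "n"); check_pos_int(m, "m")
  if (is.infinite(alpha_e)) return(n / m)
  (n / m) * alpha_e / (1 + alpha_e)
}

#' Load report for a decoder/encoder pair
#'
#' @param N,n,m Sample count, input dimension, representation dimension.
#' @param c_d Decoder complexity.
#' @param c_e Optional encoder complexity; when given, the encoder load is
#'   included.
#' @return An object of class `"load_report"`: a list with `n_samples`,
#'   `input_dim`, `rep_dim`, `decoder_load` and (optionally) `encoder_load`.
#' @export
load_report <- function(N, n, m, c_d, c_e = NULL) {
  rep <- list(n_samples = N, input_dim = n, rep_dim = m,
              decoder_load = decoder_load(N, n, m, c_d),
              encoder_load = if (!is.null(c_e)) encoder_load(N, m, c_e) else NULL)
  structure(rep, class = "load_report")
}

#' @export
print.load_report <- function(x, ...) {
  cat(sprintf("Load report: N = %d, n = %d, m = %d\n",
              x$n_samples, x$input_dim, x$rep_dim))
  cat(sprintf("  decoder load alpha_d = %.4g (%s-determined)\n", x$decoder_load,
              if (x$decoder_load > 1) "over" else "under"))
  if (!is.null(x$encoder_load))
    cat(sprintf("  encoder load alpha_e = %.4g (%s-determined)\n", x$encoder_load,
                if (x$encoder_load > 1) "over" else "under"))
  invisible(x)
}
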