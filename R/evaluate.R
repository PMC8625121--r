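#' Per-dimension Pearson correlation between true and learned representations
#'
#' For each representation dimension j, the Pearson correlation across
#' samples between the true regulator levels and the learned representation
#' values of that dimension. Alignment is by index, which is meaningful when
#' the decoder's sparsity mask is the true adjacency matrix (each hidden unit
#' is then identifiable as one specific regulator). The summary is the
#' unweighted mean over dimensions; the per-dimension vector is always
#' returned so other summaries remain computable. The statistic is invariant
#' to positive affine transforms per dimension and flips sign under negation.
#'
#' @param z_true,z_learned Matrices of equal shape (samples x dimensions).
#' @return List with `per_dimension` (length-m vector, `NA` where a column
#'   has zero variance, with a warning) and `mean` (over defined dimensions).
#' @export
representation_pcc <- function(z_true, z_learned) {
  z_true <- as.matrix(z_true); z_learned <- as.matrix(z_learned)
  if (!all(dim(z_true) == dim(z_learned)))
    stop("'z_true' and 'z_learned' must have the same shape")
  pcc <- vapply(seq_len(ncol(z_true)), function(j) {
    a <- z_true[, j]; b <- z_learned[, j]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  if (anyNA(pcc))
    warning(sprintf("%d dimension(s) had zero variance; excluded from the mean",
                    sum(is.na(pcc))))
  list(per_dimension = pcc, mean = mean(pcc, na.rm = TRUE))
}

#' Principal subspace of a data matrix
#'
#' The m-dimensional linear subspace minimizing the summed squared distances
#' between the column-centered data points and their projections — the span
#' of the top-m right singular vectors. This is the subspace a fully
#' connected single-layer linear decoder recovers, and serves as the
#' analytic oracle for the linear case.
#'
#' @param x Data matrix (samples x n).
#' @param m Subspace dimension; must not exceed the rank of the centered data.
#' @return An orthonormal (n x m) basis matrix.
#' @export
principal_subspace <- function(x, m) {
  x <- as.matrix(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  rank <- sum(sv$d > max(dim(xc)) * .Machine$double.eps * sv$d[1])
  if (m > rank)
    stop(sprintf("requested subspace dimension %d exceeds data rank %d", m, rank))
  sv$v[, seq_len(m), drop = FALSE]
}

#' Largest principal angle between two subspaces
#'
#' Both bases are orthonormalized; the largest principal angle \eqn{\theta}
#' is computed through its sine — the largest singular value of the residual
#' of one orthonormal basis after projecting out the other — which stays
#' accurate for nearly identical subspaces (the cosine formulation loses half
#' the digits near zero). Zero iff the spans are equal; pi/2 when some
#' direction of one span is orthogonal to all of the other.
#'
#' @param basis_a,basis_b (n x m) matrices of full column rank.
#' @return The largest principal angle in radians.
#' @export
subspace_angle <- function(basis_a, basis_b) {
  basis_a <- as.matrix(basis_a); basis_b <- as.matrix(basis_b)
  qa <- qr(basis_a); qb <- qr(basis_b)
  if (qa$rank < ncol(basis_a) || qb$rank < ncol(basis_b))
    stop("bases must have full column rank")
  Qa <- qr.Q(qa); Qb <- qr.Q(qb)
  resid <- Qa - Qb %*% crossprod(Qb, Qa)
  asin(min(1, svd(resid, nu = 0, nv = 0)$d[1]))
}

#' Evaluate a fitted model on test data with known regulator levels
#'
#' Representations on the test set come from gradient-descent inference for a
#' decoder fit and from a forward pass for encoder/autoencoder fits; the test
#' MSE is measured between the test data and the reconstruction of those
#' representations, and latent recovery by [representation_pcc()].
#'
#' @param object A `decoder_fit`, `encoder_fit` or `autoencoder_fit`.
#' @param x_test Test data matrix.
#' @param z_true True regulator levels for the test samples (or `NULL` to
#'   skip the PCC).
#' @param control Optional [train_control()] for decoder inference.
#' @return An object of class `"eval_report"`: list with `test_mse`,
#'   `per_dimension_pcc`, `mean_pcc`, `model_tag`.
#' @export
evaluate_model <- function(object, x_test, z_true = NULL, control = NULL) {
  x_test <- as.matrix(x_test)
  if (inherits(object, "decoder_fit")) {
    z <- infer_representations(object, x_test, control)
    recon <- reconstruct(object, z)
    tag <- "decoder"
  } else if (inherits(object, "encoder_fit")) {
    z <- predict(object, x_test, type = "representation")
    recon <- reconstruct(object$decoder, z)
    tag <- "encoder"
  } else if (inherits(object, "autoencoder_fit")) {
    z <- predict(object, x_test, type = "representation")
    recon <- forward_layers(object$dec_layers, z)
    tag <- "autoencoder"
  } else stop("'object' must be a decoder_fit, encoder_fit or autoencoder_fit")
  test_mse <- mean((x_test - recon)^2)
  pcc <- if (!is.null(z_true)) representation_pcc(z_true, z)
         else list(per_dimension = NULL, mean = NA_real_)
  structure(list(test_mse = test_mse, per_dimension_pcc = pcc$per_dimension,
                 mean_pcc = pcc$mean, model_tag = tag),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation (%s): test MSE %.6g, mean representation PCC %s\n",
              x$model_tag, x$test_mse,
              if (is.na(x$mean_pcc)) "n/a" else sprintf("%.4f", x$mean_pcc)))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `"eval_report"`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
eval_report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
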