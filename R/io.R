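# Plain-text persistence: tab-delimited matrices with row/column IDs and a
# JSON sidecar carrying the generator config and seeds, so any dataset or
# trained model is regenerable and text-diffable.

write_tsv_matrix <- function(x, path, row_prefix) {
  x <- as.matrix(x)
  rownames(x) <- sprintf("%s%d", row_prefix, seq_len(nrow(x)))
  utils::write.table(x, path, sep = "\t", quote = FALSE, col.names = NA)
}

read_tsv_matrix <- function(path) {
  x <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  dimnames(x) <- NULL
  x
}

#' Write a simulated regulatory dataset to a directory
#'
#' Writes tab-delimited expression and regulator matrices (samples in rows,
#' one-line headers of gene/regulator IDs), the network adjacency and weight
#' matrices, and a `dataset.json` sidecar with the full generator
#' configuration and seed, from which [simulate_regulatory()] regenerates the
#' dataset exactly.
#'
#' @param data A [simulate_regulatory()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(data, dir) {
  if (!inherits(data, "regulatory_data")) stop("'data' must be a regulatory_data")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gene_ids <- sprintf("gene%d", seq_len(data$config$n_genes))
  reg_ids <- sprintf("reg%d", seq_len(data$config$n_regulators))
  put <- function(x, ids, file, prefix) {
    colnames(x) <- ids
    write_tsv_matrix(x, file.path(dir, file), prefix)
  }
  put(data$x_train, gene_ids, "train_expression.tsv", "sample")
  put(data$x_test, gene_ids, "test_expression.tsv", "sample")
  put(data$z_train, reg_ids, "train_regulators.tsv", "sample")
  put(data$z_test, reg_ids, "test_regulators.tsv", "sample")
  put(data$network$adjacency, reg_ids, "adjacency.tsv", "gene")
  put(data$network$weights, reg_ids, "weights.tsv", "gene")
  meta <- list(format = "decoderfit-dataset/1",
               config = unclass(data$config), seed = data$seed,
               n_train = nrow(data$x_train), n_test = nrow(data$x_test))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "dataset.json"))
  invisible(dir)
}

#' Read a regulatory dataset written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return A `"regulatory_data"` object.
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "dataset.json"))
  if (!identical(meta$format, "decoderfit-dataset/1"))
    stop("unrecognized dataset format tag")
  config <- do.call(regnet_config, meta$config)
  network <- structure(list(adjacency = read_tsv_matrix(file.path(dir, "adjacency.tsv")),
                            weights = read_tsv_matrix(file.path(dir, "weights.tsv")),
                            config = config),
                       class = "regulatory_network")
  structure(list(x_train = read_tsv_matrix(file.path(dir, "train_expression.tsv")),
                 x_test = read_tsv_matrix(file.path(dir, "test_expression.tsv")),
                 z_train = read_tsv_matrix(file.path(dir, "train_regulators.tsv")),
                 z_test = read_tsv_matrix(file.path(dir, "test_regulators.tsv")),
                 network = network, config = config,
                 seed = as.integer(meta$seed)),
            class = "regulatory_data")
}

spec_to_meta <- function(spec) {
  list(layers = lapply(spec$layers, function(l)
         list(kind = l$kind, in_dim = l$in_dim, out_dim = l$out_dim,
              activation = l$activation, slope = l$slope)),
       loss = spec$loss %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

meta_to_layers <- function(meta, masks) {
  lapply(seq_along(meta$layers), function(i) {
    l <- meta$layers[[i]]
    if (identical(l$kind, "sparse")) sparse_layer(masks[[i]], l$activation, l$slope)
    else dense_layer(l$in_dim, l$out_dim, l$activation, l$slope)
  })
}

#' Save a fitted decoder as a plain-text checkpoint
#'
#' One directory holding per-layer weight (and mask) matrices as TSV, the
#' architecture and optimizer settings as JSON, the learned training
#' representations, and a versioned format tag.
#'
#' @param fit A `"decoder_fit"`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_model <- function(fit, dir) {
  if (!inherits(fit, "decoder_fit")) stop("'fit' must be a decoder_fit")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(fit$layers)) {
    write_tsv_matrix(fit$layers[[i]]$W,
                     file.path(dir, sprintf("weights_layer%d.tsv", i)), "out")
    if (!is.null(fit$layers[[i]]$mask))
      write_tsv_matrix(fit$layers[[i]]$mask,
                       file.path(dir, sprintf("mask_layer%d.tsv", i)), "out")
  }
  if (!is.null(fit$representations))
    write_tsv_matrix(fit$representations,
                     file.path(dir, "representations.tsv"), "sample")
  meta <- list(format = "decoderfit-model/1", spec = spec_to_meta(fit$spec),
               control = unclass(fit$control),
               loss_history = fit$loss_history)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "model.json"))
  invisible(dir)
}

#' Load a decoder checkpoint written by [write_model()]
#'
#' @param dir Checkpoint directory.
#' @return A `"decoder_fit"` (without the original training data matrix).
#' @export
read_model <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "model.json"),
                             simplifyDataFrame = FALSE)
  if (!identical(meta$format, "decoderfit-model/1"))
    stop("unrecognized model format tag")
  nl <- length(meta$spec$layers)
  masks <- lapply(seq_len(nl), function(i) {
    p <- file.path(dir, sprintf("mask_layer%d.tsv", i))
    if (file.exists(p)) read_tsv_matrix(p) else NULL
  })
  spec <- decoder_spec(meta_to_layers(meta$spec, masks),
                       loss = meta$spec$loss %||% "mse")
  weights <- lapply(seq_len(nl), function(i)
    read_tsv_matrix(file.path(dir, sprintf("weights_layer%d.tsv", i))))
  control <- do.call(train_control, meta$control)
  fit <- decoder_model(spec, weights, control)
  fit$loss_history <- as.numeric(meta$loss_history)
  rp <- file.path(dir, "representations.tsv")
  if (file.exists(rp)) fit$representations <- read_tsv_matrix(rp)
  fit
}
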