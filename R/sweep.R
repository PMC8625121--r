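#' Configuration of the load-sweep experiment
#'
#' Reproduces the simulated-data experiment end to end: for each training
#' size N and replicate, a fresh network and fresh train/test data are drawn
#' (a new test set per training set), the three models — decoder with free
#' representations, encoder on the frozen pre-trained decoder, and the naive
#' autoencoder — are trained on identical data and evaluated on the shared
#' test set, and rows with the derived loads are collected.
#'
#' The default N grid spans decoder loads from below 1 to near the n/m
#' saturation. Because one epoch contains `ceil(N / batch_size)` weight
#' updates, running a fixed epoch count would give the smallest N a few
#' hundred optimizer steps and the largest N hundreds of thousands. With a
#' finite `epoch_reference_n`, epochs are instead scaled as
#' `epochs * epoch_reference_n / N` (clamped to \[1, 20000\]), so every run
#' receives approximately the same number of weight-gradient steps — the
#' count a run of the nominal epochs would get at `N = epoch_reference_n`.
#' `Inf` disables scaling and uses the nominal epochs everywhere.
#'
#' @param n_train_grid Training sizes to sweep.
#' @param n_replicates Replicates per N (fresh data and seeds each).
#' @param test_size Test samples per run.
#' @param base_seed Master seed; all per-run seeds derive from it.
#' @param network A [regnet_config()] (the experiment uses zero noise).
#' @param decoder_control,encoder_control,ae_control [train_control()]s per
#'   model. Defaults are the experiment settings, with the decoder weight
#'   learning rate set by this package's own small grid calibration (see the
#'   methods vignette).
#' @param epoch_reference_n Reference N for the constant-step-budget epoch
#'   scaling (default 200); `Inf` disables.
#' @param min_epochs Epoch floor for the jointly trained decoder (default
#'   400): each representation row is updated once per epoch, so joint
#'   training needs a minimum number of epochs at any N, independent of the
#'   weight-step budget. Encoder and autoencoder have no free
#'   representations and scale purely by steps.
#' @param decoder_subsample_n Cap on the sample count used to train the
#'   decoder (default 2000; `Inf` disables). The decoder is already heavily
#'   over-determined at a few thousand samples (load near n/m), so training
#'   it on a sub-sample of a very large training set and reserving the full
#'   set for the encoder/autoencoder loses essentially nothing — the sweep
#'   reports the full-N load either way.
#' @param models Which models to run, a subset of
#'   `c("decoder", "encoder", "autoencoder")` (the encoder requires the
#'   decoder).
#' @return An object of class `"sweep_config"`.
#' @export
sweep_config <- function(n_train_grid = c(15, 25, 50, 100, 300, 1000, 3000,
                                          10000, 15000),
                         n_replicates = 5L, test_size = 100L, base_seed = 1L,
                         network = regnet_config(noise_sd = 0),
                         decoder_control = train_control(lr_weights = 3e-3),
                         encoder_control = train_control(lr_weights = 1e-4),
                         ae_control = train_control(lr_weights = 1e-4,
                                                    epochs = 1000L),
                         epoch_reference_n = 200, min_epochs = 400L,
                         decoder_subsample_n = 2000,
                         models = c("decoder", "encoder", "autoencoder")) {
  models <- match.arg(models, several.ok = TRUE)
  if ("encoder" %in% models && !"decoder" %in% models)
    stop("the fixed-decoder encoder requires the decoder model")
  stopifnot(length(n_train_grid) >= 1, all(n_train_grid >= 1),
            n_replicates >= 1, test_size >= 1, epoch_reference_n > 0,
            min_epochs >= 1, decoder_subsample_n >= 1)
  structure(list(n_train_grid = as.integer(n_train_grid),
                 n_replicates = as.integer(n_replicates),
                 test_size = as.integer(test_size),
                 base_seed = as.integer(base_seed), network = network,
                 decoder_control = decoder_control,
                 encoder_control = encoder_control, ae_control = ae_control,
                 epoch_reference_n = epoch_reference_n,
                 min_epochs = as.integer(min_epochs),
                 decoder_subsample_n = decoder_subsample_n, models = models),
            class = "sweep_config")
}

scale_epochs <- function(epochs, N, epoch_reference_n, floor_epochs = 1L) {
  if (!is.finite(epoch_reference_n)) return(as.integer(epochs))
  min(20000L, max(as.integer(floor_epochs),
                  as.integer(round(epochs * epoch_reference_n / N))))
}

# cheap content fingerprint used to assert the three models saw the same data
matrix_fingerprint <- function(x) {
  sprintf("%dx%d|%.10e|%.10e", nrow(x), ncol(x), sum(x), sum(x * x))
}

#' Run the load-sweep experiment
#'
#' @param config A [sweep_config()].
#' @param verbose Print per-run progress with timing.
#' @return An object of class `"load_sweep"`: a data frame with one row per
#'   (model, N, replicate) and columns `model`, `n_train`, `replicate`,
#'   `alpha_d`, `alpha_e`, `test_mse`, `mean_pcc`, `seed`, `epochs`,
#'   `data_fingerprint`, `failed`.
#' @export
run_load_sweep <- function(config = sweep_config(), verbose = TRUE) {
  if (!inherits(config, "sweep_config")) stop("'config' must be a sweep_config")
  net_cfg <- config$network
  n <- net_cfg$n_genes; m <- net_cfg$n_regulators
  c_d <- round(net_cfg$connectivity * n * m)  # sparse decoder weight count
  c_e <- n * m                                # dense encoder weight count
  rows <- list()
  for (i_n in seq_along(config$n_train_grid)) {
    N <- config$n_train_grid[i_n]
    for (rep_i in seq_len(config$n_replicates)) {
      run_seed <- config$base_seed + 1009L * (i_n - 1L) + 31L * (rep_i - 1L)
      data <- simulate_regulatory(N, config$test_size, net_cfg, seed = run_seed)
      fp <- matrix_fingerprint(data$x_train)
      alpha_d <- decoder_load(N, n, m, c_d)
      alpha_e <- encoder_load(N, m, c_e)
      dec_spec <- decoder_spec(list(sparse_layer(data$network$adjacency, "relu")))
      enc_spec <- encoder_spec(n_in = n, m_out = m)

      run_one <- function(tag, fit_fun, ctrl, epochs) {
        ctrl$epochs <- epochs
        t0 <- proc.time()[["elapsed"]]
        out <- tryCatch({
          fit <- fit_fun(ctrl)
          ev <- evaluate_model(fit, data$x_test, data$z_test,
                               control = config$decoder_control)
          list(mse = ev$test_mse, pcc = ev$mean_pcc, failed = FALSE)
        }, error = function(e) {
          warning(sprintf("%s failed at N=%d replicate %d: %s", tag, N, rep_i,
                          conditionMessage(e)))
          list(mse = NA_real_, pcc = NA_real_, failed = TRUE)
        })
        if (verbose)
          message(sprintf("N=%-6d rep %d %-11s alpha_d=%.2f  mse=%-10.4g pcc=%.4f  [%.1fs]",
                          N, rep_i, tag, alpha_d, out$mse, out$pcc,
                          proc.time()[["elapsed"]] - t0))
        data.frame(model = tag, n_train = N, replicate = rep_i,
                   alpha_d = alpha_d, alpha_e = alpha_e, test_mse = out$mse,
                   mean_pcc = out$pcc, seed = run_seed, epochs = epochs,
                   data_fingerprint = fp, failed = out$failed,
                   stringsAsFactors = FALSE)
      }

      dec_ctrl <- config$decoder_control; dec_ctrl$seed <- run_seed + 1L
      enc_ctrl <- config$encoder_control; enc_ctrl$seed <- run_seed + 2L
      ae_ctrl <- config$ae_control;       ae_ctrl$seed <- run_seed + 3L

      decoder_fit_obj <- NULL
      n_dec <- min(N, config$decoder_subsample_n)
      if ("decoder" %in% config$models)
        rows[[length(rows) + 1L]] <- run_one(
          "decoder", function(ctrl) {
            decoder_fit_obj <<- fit_decoder(
              data$x_train[seq_len(n_dec), , drop = FALSE], dec_spec, ctrl)
            decoder_fit_obj
          }, dec_ctrl,
          scale_epochs(dec_ctrl$epochs, n_dec, config$epoch_reference_n,
                       config$min_epochs))
      if ("encoder" %in% config$models)
        rows[[length(rows) + 1L]] <- run_one(
          "encoder", function(ctrl) {
            if (is.null(decoder_fit_obj)) stop("decoder training failed upstream")
            fit_encoder(data$x_train, decoder_fit_obj, enc_spec, ctrl)
          }, enc_ctrl,
          scale_epochs(enc_ctrl$epochs, N, config$epoch_reference_n))
      if ("autoencoder" %in% config$models)
        rows[[length(rows) + 1L]] <- run_one(
          "autoencoder", function(ctrl) {
            fit_autoencoder(data$x_train, enc_spec, dec_spec, ctrl)
          }, ae_ctrl,
          scale_epochs(ae_ctrl$epochs, N, config$epoch_reference_n))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  class(out) <- c("load_sweep", "data.frame")
  out
}

#' Aggregate a load sweep over replicates
#'
#' @param object A `"load_sweep"`.
#' @param ... Unused.
#' @return A data frame with one row per (model, n_train): means and standard
#'   deviations of test MSE and mean PCC, plus the loads.
#' @export
summary.load_sweep <- function(object, ...) {
  df <- as.data.frame(object)
  key <- interaction(df$model, df$n_train, drop = TRUE)
  agg <- lapply(split(df, key), function(g) {
    data.frame(model = g$model[1], n_train = g$n_train[1],
               alpha_d = g$alpha_d[1], alpha_e = g$alpha_e[1],
               mse_mean = mean(g$test_mse, na.rm = TRUE),
               mse_sd = stats::sd(g$test_mse, na.rm = TRUE),
               pcc_mean = mean(g$mean_pcc, na.rm = TRUE),
               pcc_sd = stats::sd(g$mean_pcc, na.rm = TRUE),
               n_failed = sum(g$failed), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$model, out$n_train), ]
  rownames(out) <- NULL
  out
}

#' Plot a load sweep: test MSE and representation PCC versus decoder load
#'
#' Two panels with replicate means and standard-deviation error bars per
#' model, mirroring the experiment's summary figure.
#'
#' @param x A `"load_sweep"`.
#' @param ... Passed to the underlying plot calls.
#' @export
plot.load_sweep <- function(x, ...) {
  s <- summary(x)
  models <- unique(s$model)
  cols <- stats::setNames(grDevices::hcl.colors(max(3L, length(models)),
                                                "Dark 3")[seq_along(models)],
                          models)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4.5, 4.5, 2, 1))
  on.exit(graphics::par(op))
  panel <- function(mcol, scol, ylab, log_y) {
    rng <- range(c(s[[mcol]] - s[[scol]], s[[mcol]] + s[[scol]]), na.rm = TRUE)
    if (log_y) rng[1] <- max(rng[1], 1e-12)
    graphics::plot(NA, xlim = range(s$alpha_d), ylim = rng,
                   log = if (log_y) "xy" else "x",
                   xlab = expression(alpha[d]), ylab = ylab, ...)
    for (mod in models) {
      g <- s[s$model == mod, ]
      graphics::lines(g$alpha_d, g[[mcol]], col = cols[mod], type = "b", pch = 19)
      ok <- !is.na(g[[scol]]) & g[[scol]] > 0
      if (any(ok))
        graphics::arrows(g$alpha_d[ok], pmax(g[[mcol]][ok] - g[[scol]][ok],
                                             if (log_y) 1e-12 else -Inf),
                         g$alpha_d[ok], g[[mcol]][ok] + g[[scol]][ok],
                         angle = 90, code = 3, length = 0.03, col = cols[mod])
    }
    graphics::legend("topright", legend = models, col = cols[models],
                     lty = 1, pch = 19, bty = "n", cex = 0.8)
  }
  panel("mse_mean", "mse_sd", "test MSE", TRUE)
  panel("pcc_mean", "pcc_sd", "mean representation PCC", FALSE)
  invisible(x)
}

#' Write sweep results and summary to CSV
#'
#' @param sweep A `"load_sweep"`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sweep <- function(sweep, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(sweep), file.path(dir, "sweep.csv"),
                   row.names = FALSE)
  utils::write.csv(summary(sweep), file.path(dir, "summary.csv"),
                   row.names = FALSE)
  cfg <- attr(sweep, "config")
  if (!is.null(cfg)) {
    strip <- function(x) {
      if (is.list(x)) {
        x <- lapply(x, strip)
        attributes(x) <- list(names = names(x))
      }
      x
    }
    js <- jsonlite::toJSON(strip(unclass(cfg)), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    writeLines(js, file.path(dir, "sweep_config.json"))
  }
  invisible(dir)
}
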