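# Sweep tests run the full pipeline on the reduced geometry (60 genes, 6
# regulators) so the orchestration logic is exercised in seconds.

small_sweep_config <- function(grid = c(10, 20), reps = 2L, seed = 1L,
                               models = c("decoder", "encoder", "autoencoder")) {
  sweep_config(
    n_train_grid = grid, n_replicates = reps, test_size = 15L,
    base_seed = seed, network = tiny_config(noise_sd = 0),
    decoder_control = train_control(lr_weights = 3e-3, epochs = 150),
    encoder_control = train_control(lr_weights = 1e-3, epochs = 100),
    ae_control = train_control(lr_weights = 1e-3, epochs = 200),
    epoch_reference_n = Inf, models = models)
}

test_that("sweep emits one row per model, N and replicate with exact loads", {
  cfg <- small_sweep_config()
  res <- run_load_sweep(cfg, verbose = FALSE)
  expect_s3_class(res, "load_sweep")
  expect_equal(nrow(res), 3 * 2 * 2)
  c_d <- round(0.2 * 60 * 6)
  for (i in seq_len(nrow(res)))
    expect_equal(res$alpha_d[i], decoder_load(res$n_train[i], 60, 6, c_d))
  expect_equal(unique(res$alpha_e[res$n_train == 20]),
               encoder_load(20, 6, 60 * 6))
  expect_false(any(res$failed))
})

test_that("the three models consume identical train/test data per run", {
  res <- run_load_sweep(small_sweep_config(grid = 15, reps = 2L),
                        verbose = FALSE)
  for (key in split(res, interaction(res$n_train, res$replicate)))
    expect_length(unique(key$data_fingerprint), 1L)
  # different replicates draw different data
  expect_length(unique(res$data_fingerprint), 2L)
})

test_that("sweeps are reproducible from the base seed alone", {
  cfg <- small_sweep_config(grid = 12, reps = 1L, seed = 7L)
  r1 <- run_load_sweep(cfg, verbose = FALSE)
  r2 <- run_load_sweep(cfg, verbose = FALSE)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("model subsets are honored and the encoder needs the decoder", {
  res <- run_load_sweep(small_sweep_config(grid = 12, reps = 1L,
                                           models = "decoder"),
                        verbose = FALSE)
  expect_identical(unique(res$model), "decoder")
  expect_error(sweep_config(models = c("encoder", "autoencoder")), "decoder")
})

test_that("summary aggregation matches a hand-rolled group-by oracle", {
  rows <- data.frame(
    model = rep(c("decoder", "autoencoder"), each = 3),
    n_train = 10, replicate = 1:3, alpha_d = 2.5, alpha_e = 0.1,
    test_mse = c(0.1, 0.2, 0.3, 1.0, 1.1, 1.2),
    mean_pcc = c(0.9, 0.95, 1.0, 0.5, 0.4, 0.6),
    seed = 1, epochs = 10, data_fingerprint = "x", failed = FALSE,
    stringsAsFactors = FALSE)
  class(rows) <- c("load_sweep", "data.frame")
  s <- summary(rows)
  dec <- s[s$model == "decoder", ]
  expect_equal(dec$mse_mean, mean(c(0.1, 0.2, 0.3)))
  expect_equal(dec$mse_sd, sd(c(0.1, 0.2, 0.3)))
  expect_equal(dec$pcc_mean, mean(c(0.9, 0.95, 1.0)))
  # identical rows aggregate with zero spread
  rows$test_mse <- 0.5; rows$mean_pcc <- 0.8
  s2 <- summary(rows)
  expect_true(all(s2$mse_sd == 0))
})

test_that("epoch scaling keeps the weight-update budget constant", {
  expect_identical(decoderfit:::scale_epochs(500, 200, 200), 500L)
  expect_identical(decoderfit:::scale_epochs(500, 400, 200), 250L)
  expect_identical(decoderfit:::scale_epochs(500, 100, 200), 1000L)
  expect_identical(decoderfit:::scale_epochs(500, 10000, Inf), 500L)
  # clamped at the extremes
  expect_identical(decoderfit:::scale_epochs(500, 1, 200), 20000L)
})

test_that("decoder test error is non-increasing in N on replicate means", {
  cfg <- small_sweep_config(grid = c(15, 40, 120), reps = 2L,
                            models = "decoder")
  res <- run_load_sweep(cfg, verbose = FALSE)
  s <- summary(res)
  mse <- s$mse_mean[order(s$n_train)]
  # monotone up to replicate noise: at most one inversion allowed
  expect_lte(sum(diff(mse) > 0), 1)
})

test_that("sweep results and summary write to CSV with a config snapshot", {
  res <- run_load_sweep(small_sweep_config(grid = 12, reps = 1L,
                                           models = "decoder"),
                        verbose = FALSE)
  dir <- withr::local_tempdir()
  write_sweep(res, dir)
  expect_true(all(file.exists(file.path(dir, c("sweep.csv", "summary.csv",
                                               "sweep_config.json")))))
  back <- utils::read.csv(file.path(dir, "sweep.csv"))
  expect_equal(nrow(back), nrow(res))
})
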