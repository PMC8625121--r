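test_that("reconstruction is the decoder forward map", {
  spec <- decoder_spec(list(dense_layer(4, 4)))
  ident <- decoder_model(spec, diag(4))
  z <- matrix(rnorm(12), 3, 4)
  expect_equal(reconstruct(ident, z), z)
  expect_error(reconstruct(ident, matrix(1, 2, 3)), "dimension")
})

test_that("a sparse rectified layer with the true weights reproduces the simulator", {
  d <- tiny_data(seed = 20)
  spec <- tiny_decoder_spec(d)
  truth <- decoder_model(spec, d$network$adjacency * d$network$weights)
  expect_equal(reconstruct(truth, d$z_test), d$x_test, tolerance = 1e-12)
})

test_that("single-layer scaling invariance holds exactly", {
  set.seed(21)
  w <- matrix(rnorm(50), 10, 5)
  z <- matrix(rnorm(15), 3, 5)
  spec <- decoder_spec(list(dense_layer(5, 10, "relu")))
  for (s in c(2, -3, 0.01)) {
    a <- reconstruct(decoder_model(spec, w / s), z * s)
    b <- reconstruct(decoder_model(spec, w), z)
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("training interpolates a single sample given enough capacity", {
  set.seed(22)
  x <- matrix(abs(rnorm(1 * 8)), 1, 8)
  spec <- decoder_spec(list(dense_layer(8, 8)))
  fit <- fit_decoder(x, spec, train_control(epochs = 2000, seed = 1,
                                            lr_weights = 1e-2))
  expect_lt(tail(fit$loss_history, 1), 1e-6)
})

test_that("training loss decreases and the fit is reproducible", {
  d <- tiny_data(seed = 23)
  spec <- tiny_decoder_spec(d)
  ctl <- train_control(epochs = 100, seed = 2)
  fit1 <- fit_decoder(d$x_train, spec, ctl)
  fit2 <- fit_decoder(d$x_train, spec, ctl)
  expect_lt(tail(fit1$loss_history, 1), fit1$loss_history[1])
  expect_identical(fit1$layers, fit2$layers)
  expect_identical(fit1$representations, fit2$representations)
  expect_length(fit1$loss_history, 100)
  # a different seed gives a different trajectory
  fit3 <- fit_decoder(d$x_train, spec, train_control(epochs = 100, seed = 3))
  expect_false(identical(fit1$representations, fit3$representations))
})

test_that("masked entries stay structurally zero through training", {
  d <- tiny_data(seed = 24)
  fit <- fit_decoder(d$x_train, tiny_decoder_spec(d),
                     train_control(epochs = 50, seed = 1))
  W <- coef(fit)$layer1
  expect_true(all(W[d$network$adjacency == 0] == 0))
})

test_that("a dense linear decoder recovers the principal subspace", {
  set.seed(25)
  n <- 20; m <- 3; N <- 300
  # anisotropic zero-mean Gaussian data with a clear top-m subspace
  basis <- qr.Q(qr(matrix(rnorm(n * n), n)))
  sdev <- c(8, 6, 4, rep(0.3, n - m))
  x <- matrix(rnorm(N * n), N, n) %*% diag(sdev) %*% t(basis)
  x <- scale(x, center = TRUE, scale = FALSE)
  spec <- decoder_spec(list(dense_layer(m, n)))
  fit <- fit_decoder(x, spec, train_control(epochs = 6000, seed = 4,
                                            lr_weights = 3e-3))
  oracle <- principal_subspace(x, m)
  expect_lt(subspace_angle(coef(fit)$layer1, oracle), 1e-2)
})

test_that("inference matches the normal-equations projection for a linear decoder", {
  set.seed(26)
  n <- 30; m <- 4
  w <- matrix(rnorm(n * m), n, m)
  spec <- decoder_spec(list(dense_layer(m, n)))
  dec <- decoder_model(spec, w,
                       control = train_control(infer_epochs = 5000,
                                               infer_tol = 1e-14,
                                               infer_patience = 50))
  x_new <- matrix(rnorm(5 * n), 5, n)
  z_hat <- infer_representations(dec, x_new)
  z_star <- t(solve(crossprod(w), crossprod(w, t(x_new))))
  expect_lt(max(abs(z_hat - z_star)) / max(abs(z_star)), 1e-3)
})

test_that("inference on an identity decoder returns the input", {
  spec <- decoder_spec(list(dense_layer(6, 6)))
  ident <- decoder_model(spec, diag(6),
                         control = train_control(infer_epochs = 3000,
                                                 infer_tol = 1e-14))
  x <- matrix(rnorm(18), 3, 6)
  z <- infer_representations(ident, x)
  expect_equal(unclass(z)[, ], x[, ], tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("re-inferring a training sample approaches its training loss", {
  d <- tiny_data(n_train = 30, seed = 27)
  ctl <- train_control(epochs = 800, seed = 5, infer_epochs = 1000,
                       # the rectifier makes inference non-convex; the sparse
                       # tiny geometry (~1 edge per gene) has pronounced local
                       # minima, so inference uses best-of-k restarts
                       infer_restarts = 10L)
  fit <- fit_decoder(d$x_train, tiny_decoder_spec(d), ctl)
  train_loss <- rowMeans((d$x_train - fitted(fit))^2)
  z <- infer_representations(fit, d$x_train)
  infer_loss <- attr(z, "per_sample_loss")
  expect_true(all(infer_loss <= 1.05 * train_loss + 1e-8))
})

test_that("multi-restart inference keeps per-sample best solutions", {
  d <- tiny_data(seed = 28)
  fit <- fit_decoder(d$x_train, tiny_decoder_spec(d),
                     train_control(epochs = 300, seed = 6))
  ctl1 <- fit$control; ctl1$infer_restarts <- 1L
  ctl3 <- fit$control; ctl3$infer_restarts <- 3L
  z1 <- infer_representations(fit, d$x_test, ctl1)
  z3 <- infer_representations(fit, d$x_test, ctl3)
  expect_true(all(attr(z3, "per_sample_loss") <=
                  attr(z1, "per_sample_loss") + 1e-10))
})

test_that("degenerate inputs raise informative errors", {
  d <- tiny_data(seed = 29)
  spec <- tiny_decoder_spec(d)
  bad <- d$x_train; bad[1, 1] <- NA
  expect_error(fit_decoder(bad, spec), "NA")
  expect_error(fit_decoder(d$x_train[, 1:10], spec), "dimension")
  expect_error(fit_decoder(d$x_train, spec,
                           train_control(lr_reps = 100, epochs = 400)),
               "diverged")
})

test_that("binary cross-entropy requires a sigmoid head and [0,1] data", {
  expect_error(decoder_spec(list(dense_layer(2, 6)), loss = "bce"), "sigmoid")
  spec <- decoder_spec(list(dense_layer(2, 6, "sigmoid")), loss = "bce")
  set.seed(33)
  x01 <- matrix(runif(40 * 6), 40, 6)
  expect_error(fit_decoder(x01 * 2, spec), "\\[0, 1\\]")
  fit <- fit_decoder(x01, spec, train_control(epochs = 400, seed = 1,
                                              lr_weights = 1e-2))
  expect_lt(tail(fit$loss_history, 1), fit$loss_history[1])
  # reconstructions live in (0, 1) through the sigmoid
  recon <- fitted(fit)
  expect_true(all(recon > 0 & recon < 1))
})

test_that("model methods expose the standard fit surface", {
  d <- tiny_data(seed = 30)
  fit <- fit_decoder(d$x_train, tiny_decoder_spec(d),
                     train_control(epochs = 60, seed = 1))
  expect_output(print(fit), "Decoder fit")
  s <- summary(fit)
  expect_identical(s$complexity, model_complexity(fit$layers))
  expect_equal(s$load$decoder_load,
               decoder_load(40, 60, 6, s$complexity))
  expect_equal(dim(residuals(fit)), dim(d$x_train))
  expect_equal(fitted(fit), reconstruct(fit, fit$representations))
  p <- predict(fit, d$x_test, type = "reconstruction")
  expect_equal(dim(p), dim(d$x_test))
})
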