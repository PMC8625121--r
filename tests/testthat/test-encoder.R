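test_that("the decoder is bitwise frozen during encoder training", {
  d <- tiny_data(seed = 40)
  dec <- fit_decoder(d$x_train, tiny_decoder_spec(d),
                     train_control(epochs = 300, seed = 1))
  w_before <- lapply(dec$layers, `[[`, "W")
  enc <- fit_encoder(d$x_train, dec,
                     control = train_control(lr_weights = 1e-3, epochs = 100,
                                             seed = 2))
  expect_identical(lapply(enc$decoder$layers, `[[`, "W"), w_before)
  expect_identical(lapply(dec$layers, `[[`, "W"), w_before)
})

test_that("a linear encoder on an identity decoder recovers the data map", {
  set.seed(41)
  n <- 12; m <- 3
  Zt <- matrix(rnorm(300 * m), 300, m)
  W <- matrix(rnorm(n * m), n, m)
  X <- Zt %*% t(W)
  dec <- decoder_model(decoder_spec(list(dense_layer(m, n))), W)
  enc <- fit_encoder(X, dec, encoder_spec(list(dense_layer(n, m))),
                     train_control(lr_weights = 1e-2, epochs = 600, seed = 3))
  # composed reconstruction loss reaches the least-squares optimum (zero here)
  expect_lt(tail(enc$loss_history, 1), 1e-6)
  # and the encoder agrees with the closed-form pseudo-inverse map on new data
  x_new <- matrix(rnorm(20 * m), 20, m) %*% t(W)
  z_hat <- predict(enc, x_new)
  z_star <- t(solve(crossprod(W), crossprod(W, t(x_new))))
  expect_equal(z_hat, z_star, tolerance = 1e-2, ignore_attr = TRUE)
})

test_that("zero input noise reproduces the plain variant exactly", {
  d <- tiny_data(seed = 42)
  dec <- fit_decoder(d$x_train, tiny_decoder_spec(d),
                     train_control(epochs = 200, seed = 1))
  ctl <- train_control(lr_weights = 1e-3, epochs = 80, seed = 4)
  e0 <- fit_encoder(d$x_train, dec, control = ctl, noise_sd = 0)
  e0b <- fit_encoder(d$x_train, dec, control = ctl, noise_sd = 0)
  expect_identical(coef(e0), coef(e0b))
  en <- fit_encoder(d$x_train, dec, control = ctl, noise_sd = 0.2)
  expect_false(identical(coef(e0), coef(en)))
})

test_that("denoising encoder still encodes clean training data well", {
  d <- tiny_data(n_train = 200, seed = 43)
  dec <- fit_decoder(d$x_train, tiny_decoder_spec(d),
                     train_control(epochs = 500, seed = 1))
  ctl <- train_control(lr_weights = 1e-3, epochs = 400, seed = 5)
  clean_fit <- fit_encoder(d$x_train, dec, control = ctl, noise_sd = 0)
  noisy_fit <- fit_encoder(d$x_train, dec, control = ctl, noise_sd = 0.2)
  clean_loss <- function(enc)
    mean((d$x_train - predict(enc, d$x_train, type = "reconstruction"))^2)
  expect_lt(clean_loss(noisy_fit), 2 * clean_loss(clean_fit) + 1e-6)
})

test_that("representation-target regression approximates the composed objective", {
  d <- tiny_data(n_train = 200, seed = 44)
  dec <- fit_decoder(d$x_train, tiny_decoder_spec(d),
                     train_control(epochs = 600, seed = 1))
  ctl <- train_control(lr_weights = 1e-3, epochs = 400, seed = 6)
  via_recon <- fit_encoder(d$x_train, dec, control = ctl)
  via_z <- fit_encoder(d$x_train, dec, control = ctl, target = "representation")
  z_a <- predict(via_recon, d$x_test)
  z_b <- predict(via_z, d$x_test)
  # both should land close to the decoder-defined representations
  agreement <- representation_pcc(z_a, z_b)$mean
  expect_gt(agreement, 0.8)
})

test_that("autoencoder interpolates one sample and is reproducible", {
  set.seed(45)
  x <- matrix(abs(rnorm(8)), 1, 8)
  enc_s <- encoder_spec(list(dense_layer(8, 8, "leaky_relu")))
  dec_s <- decoder_spec(list(dense_layer(8, 8)))
  ctl <- train_control(lr_weights = 1e-2, epochs = 2000, seed = 7)
  ae <- fit_autoencoder(x, enc_s, dec_s, ctl)
  expect_lt(tail(ae$loss_history, 1), 1e-5)
  ae2 <- fit_autoencoder(x, enc_s, dec_s, ctl)
  expect_identical(coef(ae), coef(ae2))
})

test_that("specification mismatches are rejected", {
  d <- tiny_data(seed = 46)
  dec <- fit_decoder(d$x_train, tiny_decoder_spec(d),
                     train_control(epochs = 20, seed = 1))
  expect_error(fit_encoder(d$x_train, dec, encoder_spec(n_in = 60, m_out = 4)),
               "dimension")
  expect_error(fit_encoder(d$x_train, dec, noise_sd = -1), "noise_sd")
  expect_error(fit_autoencoder(d$x_train, encoder_spec(n_in = 60, m_out = 4),
                               tiny_decoder_spec(d)),
               "dimensions must match")
})
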