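test_that("representation PCC is affine-invariant per dimension", {
  set.seed(8)
  z <- matrix(rgamma(200 * 5, 2), 200, 5)
  expect_equal(representation_pcc(z, z)$per_dimension, rep(1, 5))
  expect_equal(representation_pcc(z, 3 * z + 7)$mean, 1)
  # sign flip anti-symmetry
  expect_equal(representation_pcc(z, -z)$per_dimension, rep(-1, 5))
  # per-dimension scaling leaves each PCC at 1
  scaled <- sweep(z, 2, c(0.1, 1, 10, 100, 1000), `*`)
  expect_equal(representation_pcc(z, scaled)$mean, 1)
})

test_that("independent matrices have near-zero mean PCC", {
  set.seed(9)
  a <- matrix(rnorm(10000 * 4), 10000, 4)
  b <- matrix(rnorm(10000 * 4), 10000, 4)
  expect_lt(abs(representation_pcc(a, b)$mean), 0.05)
})

test_that("zero-variance dimensions are flagged and excluded", {
  set.seed(10)
  z <- matrix(rnorm(30 * 3), 30, 3)
  zl <- z
  zl[, 2] <- 5
  expect_warning(out <- representation_pcc(z, zl), "zero variance")
  expect_true(is.na(out$per_dimension[2]))
  expect_equal(out$mean, mean(out$per_dimension[c(1, 3)]))
  expect_error(representation_pcc(z, zl[1:10, ]), "shape")
})

test_that("principal subspace matches the covariance-eigenvector oracle", {
  set.seed(11)
  x <- matrix(rnorm(300 * 12), 300, 12) %*% diag(sqrt(12:1))
  for (m in c(1, 3, 5)) {
    v <- principal_subspace(x, m)
    ev <- eigen(stats::cov(scale(x, center = TRUE, scale = FALSE)),
                symmetric = TRUE)$vectors[, seq_len(m), drop = FALSE]
    expect_lt(subspace_angle(v, ev), 1e-8)
  }
})

test_that("principal subspace minimizes summed squared projection distance", {
  set.seed(12)
  x <- matrix(rnorm(100 * 8), 100, 8) %*% matrix(rnorm(64), 8, 8)
  m <- 3
  xc <- scale(x, center = TRUE, scale = FALSE)
  proj_err <- function(basis) {
    q <- qr.Q(qr(basis))
    sum((xc - xc %*% q %*% t(q))^2)
  }
  best <- proj_err(principal_subspace(x, m))
  for (i in 1:100) {
    rand <- matrix(rnorm(8 * m), 8, m)
    expect_lte(best, proj_err(rand) + 1e-10)
  }
})

test_that("points on a line are recovered and rank overreach errors", {
  direction <- c(1, 2, -2) / 3
  x <- outer(seq(-5, 5, length.out = 20), direction)
  v <- principal_subspace(x, 1)
  expect_lt(subspace_angle(v, matrix(direction)), 1e-8)
  expect_error(principal_subspace(x, 2), "rank")
})

test_that("subspace angle detects identity, rotation and orthogonality", {
  set.seed(13)
  b <- qr.Q(qr(matrix(rnorm(10 * 3), 10, 3)))
  expect_equal(subspace_angle(b, b), 0, tolerance = 1e-10)
  # rotation within the span leaves the subspace unchanged
  rot <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  expect_lt(subspace_angle(b, b %*% rot), 1e-8)
  # orthogonal complements meet at a right angle
  q <- qr.Q(qr(matrix(rnorm(10 * 6), 10, 6)))
  expect_equal(subspace_angle(q[, 1:3], q[, 4:6]), pi / 2, tolerance = 1e-8)
  expect_error(subspace_angle(cbind(b[, 1], b[, 1]), b), "rank")
})

test_that("a perfect decoder evaluates to zero error and unit correlation", {
  d <- tiny_data(seed = 14)
  spec <- tiny_decoder_spec(d)
  perfect <- decoder_model(spec, d$network$adjacency * d$network$weights,
                           control = train_control(infer_epochs = 2000,
                                                   infer_tol = 1e-12))
  ev <- evaluate_model(perfect, d$x_test, d$z_test)
  expect_s3_class(ev, "eval_report")
  expect_lt(ev$test_mse, 1e-3)
  expect_gt(ev$mean_pcc, 0.999)
  expect_identical(ev$model_tag, "decoder")
})

test_that("an untrained random model has near-zero latent recovery", {
  d <- tiny_data(n_train = 500, seed = 15)
  spec <- tiny_decoder_spec(d)
  set.seed(16)
  random_w <- matrix(rnorm(60 * 6, sd = 0.1), 60, 6) * d$network$adjacency
  rand_dec <- decoder_model(spec, random_w)
  ev <- evaluate_model(rand_dec, d$x_test, d$z_test)
  expect_lt(abs(ev$mean_pcc), 0.45)
  expect_gt(ev$test_mse, 0.1)
})

test_that("evaluation reports serialize to JSON round-trip", {
  d <- tiny_data(seed = 17)
  perfect <- decoder_model(tiny_decoder_spec(d),
                           d$network$adjacency * d$network$weights)
  ev <- evaluate_model(perfect, d$x_test, d$z_test)
  path <- withr::local_tempfile(fileext = ".json")
  eval_report_json(ev, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$test_mse, ev$test_mse)
  expect_equal(back$model_tag, "decoder")
})
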