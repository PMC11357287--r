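make_toy_dataset <- function(n = 60, h = 10, w = 6, K = 2, sep = 8,
                             seed = 5) {
  blobs <- make_gaussian_blobs(n, K, dim = h * w, separation = sep,
                               seed = seed)
  feats <- lapply(seq_len(n), function(i) {
    structure(
      list(molecule_id = paste0("m", i),
           matrix = matrix(blobs$x[i, ], h, w), s = h, N = w),
      class = "spectral_features"
    )
  })
  list(ds = feature_dataset(feats), labels = blobs$labels)
}

test_that("RBM energy matches direct substitution", {
  p <- list(W = matrix(2), a = 0.5, b = 0.25, visible_type = "bernoulli")
  expect_equal(rbm_energy(p, 0, 0), 0)
  expect_equal(rbm_energy(p, 1, 1), -2.75)
  p2 <- list(W = matrix(4), a = 0.5, b = 0.25, visible_type = "bernoulli")
  expect_equal(rbm_energy(p2, 1, 1) - rbm_energy(p, 1, 1), -2)
  expect_error(rbm_energy(p, c(1, 1), 1), "length")
})

test_that("CD-1 learns a degenerate repeated-vector dataset", {
  x <- matrix(rep(c(0.5, -0.25, 1, 0), 40), nrow = 40, byrow = TRUE)
  rbm <- rbm_train_cd(x, hidden = 16, epochs = 200, seed = 3,
                      visible_type = "gaussian")
  expect_lte(utils::tail(rbm$recon_mse, 1), 0.05)
  expect_lte(utils::tail(rbm$recon_mse, 1), rbm$recon_mse[1])
})

test_that("RBM training is bitwise reproducible and validates inputs", {
  x <- matrix(stats::rnorm(200), 20)
  r1 <- rbm_train_cd(x, 8, epochs = 5, seed = 11)
  r2 <- rbm_train_cd(x, 8, epochs = 5, seed = 11)
  expect_identical(r1$W, r2$W)
  expect_error(rbm_train_cd(x, hidden = 0, epochs = 5, seed = 1), "hidden")
})

test_that("DBN encoding has the contracted shapes and identity behaviour", {
  x <- matrix(stats::rnorm(15 * 6), 15, 6)
  # identity-like single layer: W = I, zero biases -> sigmoid(X)
  rbm <- list(W = diag(6), a = rep(0, 6), b = rep(0, 6),
              visible_type = "gaussian")
  z <- dbn_encode(list(rbm), x)
  expect_equal(z, 1 / (1 + exp(-x)), tolerance = 1e-12)
  expect_equal(nrow(z), 15)
  expect_error(dbn_encode(list(list(W = diag(4), a = rep(0, 4),
                                    b = rep(0, 4))), x),
               "shape mismatch")
})

test_that("DBN latent separates well-separated blobs", {
  toy <- make_toy_dataset(n = 60, sep = 10, seed = 8)
  dbn <- dbn_train(toy$ds$X, layer_sizes = c(32, 8), epochs = 40, seed = 2)
  Z <- dbn_encode(dbn, toy$ds$X)
  cent <- t(sapply(1:2, function(k) colMeans(Z[toy$labels == k, ])))
  d2 <- outer(rowSums(Z^2), rowSums(cent^2), "+") - 2 * Z %*% t(cent)
  acc <- mean(max.col(-d2) == toy$labels)
  expect_gte(max(acc, 1 - acc), 0.95)
})

test_that("Gaussian KL closed form matches its reference points", {
  expect_equal(gaussian_kl(0, 0), 0)
  expect_equal(gaussian_kl(2, 0), 2)
  expect_equal(gaussian_kl(c(1, 1), c(0, 0)), 1)
  mu <- matrix(c(3, 0), 1)
  expect_equal(gaussian_kl(mu), 4.5)
  expect_true(all(gaussian_kl(matrix(stats::rnorm(20), 5),
                              matrix(stats::rnorm(20), 5)) >= 0))
})

test_that("every autoencoder reduces reconstruction loss from epoch 0", {
  toy <- make_toy_dataset(n = 40, seed = 6)
  for (kind in c("cae", "vae", "aae")) {
    m <- train_autoencoder(toy$ds, kind, latent_dim = 6, epochs = 8,
                           seed = 4)
    curve <- if (kind == "vae") m$recon_curve else m$loss_curve
    expect_lt(utils::tail(curve, 1), curve[1])
    expect_equal(ncol(encode_latent(m, toy$ds$X)), 6)
  }
})

test_that("VAE total loss is never below its reconstruction term", {
  toy <- make_toy_dataset(n = 30, seed = 2)
  m <- train_autoencoder(toy$ds, "vae", latent_dim = 4, epochs = 6,
                         seed = 9)
  expect_true(all(m$kl_curve >= 0))
  expect_true(all(m$loss_curve >= m$recon_curve))
})

test_that("training is reproducible bit-for-bit under a fixed seed", {
  toy <- make_toy_dataset(n = 24, seed = 3)
  for (kind in c("cae", "vae", "aae")) {
    m1 <- train_autoencoder(toy$ds, kind, latent_dim = 4, epochs = 3,
                            seed = 7)
    m2 <- train_autoencoder(toy$ds, kind, latent_dim = 4, epochs = 3,
                            seed = 7)
    expect_identical(m1$enc_params, m2$enc_params)
    expect_identical(m1$loss_curve, m2$loss_curve)
  }
})

test_that("an untrained discriminator starts near the 2 log 2 loss", {
  toy <- make_toy_dataset(n = 40, seed = 13)
  rng <- local_rng(1)
  disc_layers <- list(layer_dense(4, 64, act = "relu"),
                      layer_dense(64, 1, act = "sigmoid"))
  disc_params <- stack_init(disc_layers, rng)
  zp <- matrix(rng$rnorm(200 * 4), 200)
  zq <- matrix(rng$rnorm(200 * 4, mean = 0.3), 200)
  dp <- stack_fwd(disc_layers, disc_params, zp)$out
  dq <- stack_fwd(disc_layers, disc_params, zq)$out
  loss <- -mean(log(dp)) - mean(log(1 - dq))
  expect_lt(abs(loss - 2 * log(2)) / (2 * log(2)), 0.2)
})

test_that("joint fine-tuning with lambda 0 matches plain training", {
  toy <- make_toy_dataset(n = 24, seed = 3)
  m <- train_autoencoder(toy$ds, "aae", latent_dim = 4, epochs = 3,
                         seed = 7)
  fit <- kmeans_fit(encode_latent(m, toy$ds$X), 2, seed = 1)
  m0 <- joint_finetune(m, toy$ds, fit, lambda = 0, outer_steps = 2,
                       seed = 5)
  # the recon-only path: same trainer, same rng stream, lambda absent
  rng <- local_rng(derive_seed(5, "joint"))
  mref <- molspec:::train_deterministic_ae(m, toy$ds$X, epochs = 1,
                                           lr = 1e-3, batch_size = 16,
                                           rng = rng)
  expect_equal(m0$joint_loss_curve[1],
               utils::tail(mref$loss_curve, 1) + 0,
               tolerance = 1e-10)
  expect_error(joint_finetune(m, toy$ds, fit, lambda = -1), "nonnegative")
})

test_that("a large cluster weight pulls latents toward their centroids", {
  toy <- make_toy_dataset(n = 24, seed = 3)
  m <- train_autoencoder(toy$ds, "aae", latent_dim = 4, epochs = 5,
                         seed = 7)
  Z0 <- encode_latent(m, toy$ds$X)
  fit <- kmeans_fit(Z0, 2, seed = 1)
  d0 <- mean(rowSums((Z0 - fit$centroids[fit$labels, ])^2))
  m2 <- joint_finetune(m, toy$ds, fit, lambda = 50, outer_steps = 5,
                       epochs_per_step = 2, seed = 5,
                       update_assignment = FALSE)
  Z1 <- encode_latent(m2, toy$ds$X)
  d1 <- mean(rowSums((Z1 - fit$centroids[fit$labels, ])^2))
  expect_lt(d1, d0)
})

test_that("cluster loss with one cluster equals the latent scatter", {
  rng <- local_rng(8)
  Z <- matrix(rng$rnorm(30), 10, 3)
  mu <- colMeans(Z)
  lcl <- sum((Z - matrix(mu, 10, 3, byrow = TRUE))^2)
  expect_equal(lcl, sum(apply(Z, 2, function(c) sum((c - mean(c))^2))),
               tolerance = 1e-10)
})
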