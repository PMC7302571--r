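# Linear-activation configurations make the autoencoder comparable to
# closed-form linear algebra oracles: the optimal rank-k reconstruction
# error is the sum of discarded covariance eigenvalues (PCA truncation).

linear_cfg <- function(epochs, lr = 0.5, mom = 0.9)
  ae_config(epochs = epochs, learning_rate = lr, momentum = mom,
            encoder_activation = "linear", decoder_activation = "linear")

pca_floor <- function(X, k) {
  ev <- eigen(crossprod(scale(X, scale = FALSE)) / nrow(X),
              symmetric = TRUE, only.values = TRUE)$values
  sum(ev[(k + 1):ncol(X)]) / ncol(X)
}

test_that("data in an exact 10-dim subspace reconstructs to MSE <= 1e-6", {
  set.seed(3)
  B <- matrix(rnorm(100 * 10), 100, 10) %*% matrix(rnorm(10 * 30), 10, 30)
  B <- (B - min(B)) / (max(B) - min(B))
  ds <- spectral_dataset(B, seq_len(30) + 499)
  st <- train_autoencoder(ds, 10, linear_cfg(5000), seed = 1)
  expect_lt(st$step_mse, 1e-6)
  expect_lt(reconstruct(st, ds)$mse, 1e-6)
})

test_that("an identity-capable single step drives MSE to ~0", {
  ds <- tiny_dataset(n = 12, d = 6, seed = 5)
  st <- train_autoencoder(ds, 6, linear_cfg(5000), seed = 2)
  expect_lt(st$step_mse, 1e-6)
})

test_that("a single linear step approaches the PCA rank-k optimum", {
  set.seed(42)
  Z <- matrix(rnorm(120 * 12), 120, 12) %*% matrix(rnorm(12 * 25), 12, 25)
  Z <- Z + matrix(rnorm(120 * 25, sd = 0.3), 120, 25)
  Z <- (Z - min(Z)) / (max(Z) - min(Z))
  ds <- spectral_dataset(Z, seq_len(25) + 499)
  st <- train_autoencoder(ds, 5, linear_cfg(4000, lr = 1), seed = 1)
  expect_lt(st$step_mse, 1.05 * pca_floor(Z, 5))
})

test_that("training is deterministic under a seed and validates its inputs", {
  ds <- tiny_dataset(n = 10, d = 8, seed = 7)
  a <- train_autoencoder(ds, c(4, 2), ae_config(epochs = 40), seed = 3)
  b <- train_autoencoder(ds, c(4, 2), ae_config(epochs = 40), seed = 3)
  expect_identical(a$steps, b$steps)
  expect_identical(a$step_mse, b$step_mse)
  c2 <- train_autoencoder(ds, c(4, 2), ae_config(epochs = 40), seed = 4)
  expect_false(identical(a$steps, c2$steps))

  expect_error(train_autoencoder(ds, c(4, 4)),
               class = "nirparity_bad_step_dims")
  expect_error(train_autoencoder(ds, c(2, 4)),
               class = "nirparity_bad_step_dims")
  unscaled <- spectral_dataset(matrix(rnorm(40, sd = 5), 10, 4),
                               500:503)
  expect_error(train_autoencoder(unscaled, 2),
               class = "nirparity_unscaled_input")
})

test_that("encoding preserves N, labels and final code dimension", {
  ds <- tiny_dataset(n = 9, d = 8, seed = 11)
  st <- train_autoencoder(ds, c(5, 3), ae_config(epochs = 30), seed = 1)
  enc <- encode_spectra(st, ds)
  expect_equal(dim(enc$codes), c(9, 3))
  expect_identical(enc$labels, ds$labels)
  expect_identical(encode_spectra(st, ds)$codes, enc$codes)

  small <- tiny_dataset(n = 2, d = 3)
  expect_error(encode_spectra(st, small),
               class = "nirparity_dim_mismatch")
})

test_that("encoding is row-permutation equivariant", {
  ds <- tiny_dataset(n = 8, d = 6, seed = 13)
  st <- train_autoencoder(ds, c(4, 2), ae_config(epochs = 30), seed = 1)
  perm <- c(5, 1, 8, 2, 7, 3, 6, 4)
  expect_equal(encode_spectra(st, ds[perm])$codes,
               encode_spectra(st, ds)$codes[perm, ])
})

test_that("reconstruct agrees with the recorded per-step training MSE", {
  ds <- tiny_dataset(n = 10, d = 8, seed = 17)
  st <- train_autoencoder(ds, c(5, 3), ae_config(epochs = 50), seed = 2)
  # step 1 decodes straight back to the original space, so the full-chain
  # MSE and the stored per-step MSE coincide there
  expect_equal(reconstruct(st, ds, through_step = 1)$mse, st$step_mse[1])
  # deeper steps are tabulated against their own input
  expect_equal(nirparity:::step_local_mse(st, ds, 2L), st$step_mse[2])
  expect_error(reconstruct(st, ds, through_step = 3),
               class = "nirparity_bad_index")
})

test_that("a zero-weight linear stack reconstructs at the data's variance", {
  set.seed(19)
  X <- scale(matrix(rnorm(400 * 6), 400, 6))  # centered, unit variance
  ds <- spectral_dataset(X, 500:505)
  step <- nirparity:::new_ae_step(matrix(0, 3, 6), numeric(3),
                                  matrix(0, 6, 3), numeric(6),
                                  "linear", "linear")
  st <- structure(list(steps = list(step), step_mse = NA_real_,
                       input_dim = 6L, code_dim = 3L,
                       config = ae_config(), seed = 0L),
                  class = "autoencoder_stack")
  # predicting the constant 0 for centered unit-variance data gives
  # MSE = mean(x^2) ~ 1 (exactly (n-1)/n after scale())
  expect_equal(reconstruct(st, ds)$mse, mean(X^2), tolerance = 1e-12)
  expect_equal(reconstruct(st, ds)$mse, 1, tolerance = 0.01)
})

test_that("training-set MSE is non-increasing in the epoch budget", {
  ds <- tiny_dataset(n = 12, d = 8, seed = 23)
  budgets <- c(20, 80, 320, 1280)
  mses <- vapply(budgets, function(e)
    train_autoencoder(ds, 4, ae_config(epochs = e), seed = 1)$step_mse,
    0)
  expect_true(all(diff(mses) <= 1e-10))
})

test_that("10-dim codes of effect-bearing spectra retain class signal", {
  cfg <- synthetic_config(n_parous = 60, n_nulliparous = 60,
                          grid_low_nm = 500, grid_high_nm = 800,
                          effect_size = 2, seed = 31)
  ds <- generate_spectra(cfg)
  spec <- fit_scaler(ds, preprocess_spec(500, 800))
  sc <- apply_scaler(ds, spec)
  st <- train_autoencoder(sc, c(32, 10), ae_config(epochs = 80),
                          seed = 1)
  enc <- encode_spectra(st, sc)
  codes_ds <- spectral_dataset(enc$codes, seq_len(10),
                               labels = enc$labels)
  acc <- nirparity:::centroid_holdout_accuracy(codes_ds, seed = 2)
  expect_gt(acc, 0.8)  # well above the 0.5 chance rate
})
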