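#' Training settings for the stepwise autoencoder
#'
#' Each compression step is a single-hidden-layer autoencoder trained by
#' full-batch gradient descent with momentum for a fixed epoch budget.
#' Encoder units are logistic by default (inputs must then lie in
#' [0, 1]; see [fit_scaler()]), the decoder output is linear so
#' reconstruction targets are unbounded. Setting both activations to
#' `"linear"` makes a step equivalent to an unregularized linear
#' autoencoder, whose optimal reconstruction error is the PCA truncation
#' error -- useful as an independent check.
#'
#' @param epochs gradient-descent epochs per step.
#' @param learning_rate step size on the mean-square-error gradient.
#' @param momentum classical momentum coefficient.
#' @param encoder_activation,decoder_activation `"logistic"` or
#'   `"linear"`.
#' @return an object of class `ae_config`.
#' @export
ae_config <- function(epochs = 1000, learning_rate = 0.5, momentum = 0.9,
                      encoder_activation = c("logistic", "linear"),
                      decoder_activation = c("linear", "logistic")) {
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 momentum = momentum,
                 encoder_activation = match.arg(encoder_activation),
                 decoder_activation = match.arg(decoder_activation)),
            class = "ae_config")
}

#' @noRd
act_fun <- function(name) {
  switch(name,
         logistic = list(f = function(z) 1 / (1 + exp(-z)),
                         df = function(a) a * (1 - a)),
         linear = list(f = identity, df = function(a) 1))
}

#' @noRd
new_ae_step <- function(W_enc, b_enc, W_dec, b_dec,
                        encoder_activation, decoder_activation) {
  list(input_dim = ncol(W_enc), code_dim = nrow(W_enc),
       W_enc = W_enc, b_enc = b_enc, W_dec = W_dec, b_dec = b_dec,
       encoder_activation = encoder_activation,
       decoder_activation = decoder_activation)
}

# Train one autoencoder step (input X [N x d] -> code [N x k] -> X^hat)
# by full-batch momentum gradient descent on mean(E^2) over all entries.
#' @noRd
train_ae_step <- function(X, code_dim, config) {
  n <- nrow(X); d <- ncol(X); k <- code_dim
  enc <- act_fun(config$encoder_activation)
  dec <- act_fun(config$decoder_activation)
  W1 <- matrix(stats::runif(k * d, -0.1, 0.1), k, d)
  b1 <- stats::runif(k, -0.1, 0.1)
  W2 <- matrix(stats::runif(d * k, -0.1, 0.1), d, k)
  b2 <- stats::runif(d, -0.1, 0.1)
  vW1 <- matrix(0, k, d); vb1 <- numeric(k)
  vW2 <- matrix(0, d, k); vb2 <- numeric(d)
  lr <- config$learning_rate; mom <- config$momentum
  scale <- 2 / (n * d)  # d/dE of mean squared entry error
  best <- list(loss = Inf)
  for (ep in seq_len(config$epochs)) {
    H <- enc$f(tcrossprod(X, W1) + rep(b1, each = n))      # N x k
    Xh <- dec$f(tcrossprod(H, W2) + rep(b2, each = n))     # N x d
    E <- Xh - X
    loss <- mean(E^2)
    if (!is.finite(loss) || loss > 1.5 * best$loss) {
      # divergence safeguard ("bold driver"): back off to the best
      # weights seen, halve the step size and drop the momentum state;
      # deterministic, so seeded runs remain reproducible
      lr <- lr / 2
      if (lr < 1e-12)
        np_stop("nirparity_nan_loss",
                "autoencoder training diverged at epoch %d and the learning rate collapsed; rescale inputs or lower the initial rate",
                ep)
      W1 <- best$W1; b1 <- best$b1; W2 <- best$W2; b2 <- best$b2
      vW1[] <- 0; vb1[] <- 0; vW2[] <- 0; vb2[] <- 0
      next
    }
    if (loss < best$loss)
      best <- list(loss = loss, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    dZ2 <- scale * E * dec$df(Xh)                          # N x d
    gW2 <- crossprod(dZ2, H); gb2 <- colSums(dZ2)
    dH <- dZ2 %*% W2                                       # N x k
    dZ1 <- dH * enc$df(H)
    gW1 <- crossprod(dZ1, X); gb1 <- colSums(dZ1)
    vW1 <- mom * vW1 - lr * gW1; W1 <- W1 + vW1
    vb1 <- mom * vb1 - lr * gb1; b1 <- b1 + vb1
    vW2 <- mom * vW2 - lr * gW2; W2 <- W2 + vW2
    vb2 <- mom * vb2 - lr * gb2; b2 <- b2 + vb2
  }
  step <- new_ae_step(W1, b1, W2, b2,
                      config$encoder_activation, config$decoder_activation)
  recon <- step_decode(step, step_encode(step, X))
  mse <- mean((recon - X)^2)
  if (is.finite(best$loss) && best$loss < mse) {
    # keep the best-so-far weights if the last epochs drifted upward
    step <- new_ae_step(best$W1, best$b1, best$W2, best$b2,
                        config$encoder_activation,
                        config$decoder_activation)
    recon <- step_decode(step, step_encode(step, X))
    mse <- mean((recon - X)^2)
  }
  list(step = step, mse = mse)
}

#' @noRd
step_encode <- function(step, X) {
  act_fun(step$encoder_activation)$f(
    tcrossprod(X, step$W_enc) + rep(step$b_enc, each = nrow(X)))
}

#' @noRd
step_decode <- function(step, H) {
  act_fun(step$decoder_activation)$f(
    tcrossprod(H, step$W_dec) + rep(step$b_dec, each = nrow(H)))
}

#' Train a stepwise (stacked) autoencoder
#'
#' Compresses spectra through a sequence of strictly decreasing code
#' sizes (default 256, 64, 10, i.e. three steps down to a 10-feature
#' code). Training is greedy and layer-wise: step 1 learns to
#' reconstruct the input, step i > 1 learns to reconstruct the codes
#' emitted by step i-1. Each step's reconstruction mean-square error on
#' its own training input is recorded in `step_mse`. Deterministic under
#' a fixed seed.
#'
#' @param train a `spectral_dataset`; values must lie in [0, 1] when the
#'   encoder activation is logistic (use [fit_scaler()]/[apply_scaler()]).
#' @param step_dims strictly decreasing integer code sizes; the last is
#'   the final code dimension.
#' @param config an [ae_config()].
#' @param seed integer RNG seed for weight initialization.
#' @return an object of class `autoencoder_stack` with fields `steps`,
#'   `step_mse`, `input_dim`, `code_dim`, `config`, `seed`.
#' @export
train_autoencoder <- function(train, step_dims = c(256, 64, 10),
                              config = ae_config(), seed = 1) {
  validate_spectral_dataset(train)
  step_dims <- as.integer(step_dims)
  np_assert(length(step_dims) >= 1 && all(diff(step_dims) < 0) &&
              step_dims[1] <= ncol(train$absorbance),
            "nirparity_bad_step_dims",
            "step_dims must be strictly decreasing and start at or below the input dimension")
  X <- unname(train$absorbance)
  if (config$encoder_activation == "logistic" &&
      (min(X) < 0 || max(X) > 1))
    np_stop("nirparity_unscaled_input",
            "logistic encoder units require inputs in [0, 1]; apply min-max scaling first")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  steps <- vector("list", length(step_dims))
  mses <- numeric(length(step_dims))
  for (i in seq_along(step_dims)) {
    fit <- train_ae_step(X, step_dims[i], config)
    steps[[i]] <- fit$step
    mses[i] <- fit$mse
    X <- step_encode(fit$step, X)
  }
  structure(list(steps = steps, step_mse = mses,
                 input_dim = steps[[1]]$input_dim,
                 code_dim = step_dims[length(step_dims)],
                 config = config, seed = as.integer(seed)),
            class = "autoencoder_stack")
}

#' @export
print.autoencoder_stack <- function(x, ...) {
  dims <- c(x$input_dim, vapply(x$steps, `[[`, 0L, "code_dim"))
  cat(sprintf("autoencoder_stack: %s\n", paste(dims, collapse = " -> ")))
  cat("  step reconstruction MSE:",
      paste(formatC(x$step_mse, format = "g", digits = 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' Encode spectra to the stack's final code space
#'
#' Applies the encoder half of every step in order. Labels, sample ids
#' and cohort tags are carried through unchanged.
#'
#' @param stack an `autoencoder_stack`.
#' @param dataset a `spectral_dataset` with the stack's input dimension,
#'   scaled the same way as the training data.
#' @return an object of class `encoded_dataset`: fields `codes` (N x k
#'   matrix), `labels`, `sample_ids`, `cohort`, `encoder_fingerprint`.
#' @export
encode_spectra <- function(stack, dataset) {
  np_assert(inherits(stack, "autoencoder_stack"), "nirparity_bad_type",
            "not an autoencoder_stack")
  X <- encode_matrix(stack, dataset$absorbance, length(stack$steps))
  structure(list(codes = X,
                 labels = dataset$labels,
                 sample_ids = dataset$sample_ids,
                 cohort = dataset$cohort,
                 encoder_fingerprint = stack_fingerprint(stack)),
            class = "encoded_dataset")
}

#' @noRd
encode_matrix <- function(stack, X, through_step) {
  np_assert(ncol(X) == stack$input_dim, "nirparity_dim_mismatch",
            "dataset has %d features but the stack expects %d",
            ncol(X), stack$input_dim)
  X <- unname(X)
  for (i in seq_len(through_step)) X <- step_encode(stack$steps[[i]], X)
  X
}

#' @noRd
stack_fingerprint <- function(stack) {
  dims <- paste(c(stack$input_dim,
                  vapply(stack$steps, `[[`, 0L, "code_dim")), collapse = "-")
  sprintf("ae[%s]seed%d", dims, stack$seed)
}

#' Reconstruct spectra through part of the stack
#'
#' Encodes the dataset through steps `1..through_step`, then decodes back
#' through the matching decoders to the original feature space, and
#' reports the reconstruction together with its mean-square error against
#' the dataset (mean over all matrix entries). Note this differs from the
#' per-step `step_mse` recorded at training time for steps beyond the
#' first: `step_mse[i]` measures how well step i reconstructs its own
#' input (the codes of step i-1), whereas this function always measures
#' error in the original space.
#'
#' @param stack an `autoencoder_stack`.
#' @param dataset a `spectral_dataset` with the stack's input dimension.
#' @param through_step how deep to encode before decoding (defaults to
#'   the full stack).
#' @return list with `reconstruction` (N x D matrix) and `mse`.
#' @export
reconstruct <- function(stack, dataset, through_step = length(stack$steps)) {
  np_assert(through_step >= 1 && through_step <= length(stack$steps),
            "nirparity_bad_index", "through_step out of range")
  X0 <- unname(dataset$absorbance)
  H <- encode_matrix(stack, X0, through_step)
  for (i in rev(seq_len(through_step))) H <- step_decode(stack$steps[[i]], H)
  list(reconstruction = H, mse = mean((H - X0)^2))
}

# Local reconstruction error of a single step on (the encoding of) a
# dataset -- the quantity tabulated as step_mse during training.
#' @noRd
step_local_mse <- function(stack, dataset, step) {
  Xin <- encode_matrix(stack, unname(dataset$absorbance), step - 1L)
  s <- stack$steps[[step]]
  mean((step_decode(s, step_encode(s, Xin)) - Xin)^2)
}

# Save/restore .Random.seed so seeded trainers do not disturb the
# caller's RNG stream.
#' @noRd
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

#' @noRd
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}
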