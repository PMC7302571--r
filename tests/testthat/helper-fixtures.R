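# Small in-code fixtures shared across test files. Everything is built
# programmatically so the suite carries no data files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A tiny labeled dataset on an arbitrary short grid.
tiny_dataset <- function(n = 6, d = 5, seed = 1, labels = TRUE) {
  set.seed(seed)
  spectral_dataset(matrix(runif(n * d), n, d),
                   wavelengths = seq(500, by = 1, length.out = d),
                   labels = if (labels) rep_len(c(0L, 1L), n))
}

# Encoded-feature fixture for classifier tests.
encoded_fixture <- function(X, labels) {
  structure(list(codes = X, labels = as.integer(labels),
                 sample_ids = paste0("s", seq_len(nrow(X))),
                 cohort = NULL, encoder_fingerprint = "fixture"),
            class = "encoded_dataset")
}

# Two well-separated Gaussian classes in k dimensions; `gap` is the
# between-mean distance per coordinate.
gaussian_classes <- function(n_per_class = 40, k = 10, gap = 2,
                             seed = 9) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * k, 0), n_per_class, k),
             matrix(rnorm(n_per_class * k, gap), n_per_class, k))
  encoded_fixture(X, rep(c(0L, 1L), each = n_per_class))
}

# Verify linear separability of a fixture along the mean-difference
# direction (margin-check oracle): positive gap means a linear rule
# classifies the sample perfectly.
margin_gap <- function(enc) {
  X <- enc$codes; y <- enc$labels
  w <- colMeans(X[y == 1L, , drop = FALSE]) -
    colMeans(X[y == 0L, , drop = FALSE])
  pr <- drop(X %*% w)
  min(pr[y == 1L]) - max(pr[y == 0L])
}

# A fast pipeline configuration on a narrow wavelength window, for
# end-to-end tests where runtime matters more than spectral realism.
fast_config <- function(window_high = 700, steps = c(32, 10),
                        epochs = 60, pipeline = "encoded-ann", ...) {
  pipeline_config(pipeline = pipeline,
                  preprocess = preprocess_spec(500, window_high),
                  step_dims = steps,
                  ae = ae_config(epochs = epochs), ...)
}

# Field-by-field equality of two spectral datasets.
ds_equal_helper <- function(a, b) {
  isTRUE(all.equal(a$wavelengths, b$wavelengths)) &&
    isTRUE(all.equal(unname(a$absorbance), unname(b$absorbance))) &&
    identical(a$labels, b$labels) &&
    identical(a$sample_ids, b$sample_ids) &&
    identical(a$cohort, b$cohort)
}

# Exhaustive pairwise-concordance AUC oracle (ties count 1/2),
# independent of the ROC construction under test.
concordance_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
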