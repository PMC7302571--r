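#' Levenberg-Marquardt training configuration
#'
#' Controls the damped Gauss-Newton loop used by [lm_fit()]. The damping
#' factor mu is decreased (times `mu_down`) after every accepted step and
#' increased (times `mu_up`) after every rejected one; it must stay
#' within [1e-12, 1e12] or training stops with a diagnostic. Training
#' also stops at `max_iterations`, when the infinity norm of the SSE
#' gradient falls below `gradient_tolerance`, or when an accepted step
#' improves the mean-square error by less than `min_mse_delta`.
#'
#' @param mu_init initial damping.
#' @param mu_up,mu_down damping multipliers on reject/accept.
#' @param max_iterations iteration cap.
#' @param gradient_tolerance stop when `max(abs(grad))` drops below this.
#' @param min_mse_delta stop when an accepted step improves MSE by less.
#' @param seed RNG seed for weight initialization.
#' @return an object of class `lm_config`.
#' @export
lm_config <- function(mu_init = 1e-3, mu_up = 10, mu_down = 0.1,
                      max_iterations = 200, gradient_tolerance = 1e-7,
                      min_mse_delta = 1e-9, seed = 1) {
  structure(list(mu_init = mu_init, mu_up = mu_up, mu_down = mu_down,
                 max_iterations = as.integer(max_iterations),
                 gradient_tolerance = gradient_tolerance,
                 min_mse_delta = min_mse_delta, seed = as.integer(seed)),
            class = "lm_config")
}

#' Construct a feed-forward parity classifier
#'
#' The standard model is a one-hidden-layer network with (default) ten
#' logistic hidden units and a logistic output unit, so scores lie in
#' (0, 1). `hidden_units = 0` with `activation = "identity"` degenerates
#' to a single linear unit (ordinary linear least squares) -- a
#' configuration used only to validate the optimizer against the
#' closed-form solution.
#'
#' Weights are initialized uniform(-0.5, 0.5) scaled by 1/sqrt(fan-in),
#' under the training seed.
#'
#' @param input_dim number of input features.
#' @param hidden_units hidden layer width (default 10; 0 = no hidden
#'   layer).
#' @param activation `"logistic"` (default) or `"identity"` (test-only).
#' @param threshold decision cutoff: predicted label is 1 iff
#'   score > threshold (strict; a score exactly at the threshold is
#'   labeled 0).
#' @return an object of class `ann_classifier` with weight fields `W1`,
#'   `b1`, `W2`, `b2` (W1/b1 `NULL` when `hidden_units = 0`).
#' @export
ann_classifier <- function(input_dim, hidden_units = 10,
                           activation = c("logistic", "identity"),
                           threshold = 0.5) {
  activation <- match.arg(activation)
  h <- as.integer(hidden_units)
  model <- structure(list(input_dim = as.integer(input_dim),
                          hidden_units = h, activation = activation,
                          threshold = threshold,
                          W1 = NULL, b1 = NULL, W2 = NULL, b2 = NULL),
                     class = "ann_classifier")
  init_weights(model)
}

#' @noRd
init_weights <- function(model) {
  d <- model$input_dim; h <- model$hidden_units
  u <- function(n, fan_in) stats::runif(n, -0.5, 0.5) / sqrt(fan_in)
  if (h > 0) {
    model$W1 <- matrix(u(h * d, d), h, d)
    model$b1 <- u(h, d)
    model$W2 <- matrix(u(h, h), 1, h)
    model$b2 <- u(1, h)
  } else {
    model$W2 <- matrix(u(d, d), 1, d)
    model$b2 <- u(1, d)
  }
  model
}

#' @noRd
pack_params <- function(m) {
  c(if (!is.null(m$W1)) as.vector(m$W1), m$b1, as.vector(m$W2), m$b2)
}

#' @noRd
unpack_params <- function(m, theta) {
  i <- 0L
  take <- function(n) {
    v <- theta[(i + 1L):(i + n)]; i <<- i + n; v
  }
  if (m$hidden_units > 0) {
    m$W1 <- matrix(take(m$hidden_units * m$input_dim),
                   m$hidden_units, m$input_dim)
    m$b1 <- take(m$hidden_units)
    m$W2 <- matrix(take(m$hidden_units), 1, m$hidden_units)
  } else {
    m$W2 <- matrix(take(m$input_dim), 1, m$input_dim)
  }
  m$b2 <- take(1L)
  m
}

# Forward pass; returns scores and, when jacobian = TRUE, the N x P
# matrix S = d score / d theta assembled by backpropagation (theta
# packed as in pack_params).
#' @noRd
ann_forward <- function(m, X, jacobian = FALSE) {
  n <- nrow(X)
  act <- act_fun(if (m$activation == "logistic") "logistic" else "linear")
  if (m$hidden_units > 0) {
    H <- act$f(tcrossprod(X, m$W1) + rep(m$b1, each = n))
    z2 <- drop(H %*% t(m$W2)) + m$b2
  } else {
    H <- NULL
    z2 <- drop(X %*% t(m$W2)) + m$b2
  }
  s <- act$f(z2)
  if (!jacobian) return(list(scores = s))
  ds_dz2 <- if (m$activation == "logistic") s * (1 - s) else rep(1, n)
  if (m$hidden_units > 0) {
    G <- (ds_dz2 * matrix(m$W2, n, m$hidden_units, byrow = TRUE)) *
      act$df(H)                                       # N x h = ds/dZ1
    # params are packed column-major (as.vector(W1)), so the W1 block is
    # ordered input-by-input: columns (j = 1..h) for each input l
    J_W1 <- do.call(cbind, lapply(seq_len(ncol(X)),
                                  function(l) G * X[, l]))
    S <- cbind(J_W1, G, ds_dz2 * H, ds_dz2)
  } else {
    S <- cbind(ds_dz2 * X, ds_dz2)
  }
  list(scores = s, S = S)
}

#' Train the classifier by Levenberg-Marquardt optimization
#'
#' Minimizes the sum of squared residuals e = label - score over all
#' weights and biases. Each iteration solves the damped normal equations
#' `(J'J + mu I) delta = J'e` (J being the score Jacobian assembled by
#' backpropagation); the step is accepted, and mu decreased, only if it
#' reduces the sum-of-squares error, otherwise it is rejected and mu
#' increased. When the parameter count exceeds the sample count the
#' equivalent dual system `delta = J'(JJ' + mu I)^{-1} e` is solved
#' instead, which keeps raw-spectrum models (1851 inputs) tractable.
#'
#' @param model an [ann_classifier()] (its weights are re-initialized
#'   under `config$seed`).
#' @param data an `encoded_dataset` or `spectral_dataset` with binary
#'   labels.
#' @param config an [lm_config()].
#' @return the trained `ann_classifier`, with attribute `"trace"`: a
#'   data frame of per-iteration SSE, mu and acceptance, plus a
#'   `"stop_reason"` attribute.
#' @export
lm_fit <- function(model, data, config = lm_config()) {
  X <- design_matrix(data, model)
  y <- data$labels
  np_assert(!is.null(y) && all(y %in% c(0L, 1L)), "nirparity_bad_label",
            "training data must carry binary 0/1 labels")
  np_assert(all(is.finite(X)), "nirparity_nonfinite",
            "training inputs contain non-finite values")
  np_assert(nrow(X) >= 2, "nirparity_too_small",
            "need at least 2 training samples")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  model <- init_weights(model)

  theta <- pack_params(model)
  p <- length(theta)
  n <- nrow(X)
  fw <- ann_forward(model, X, jacobian = TRUE)
  e <- y - fw$scores
  sse <- sum(e^2)
  mu <- config$mu_init
  trace <- list()
  stop_reason <- "max_iterations"
  for (it in seq_len(config$max_iterations)) {
    g <- 2 * drop(crossprod(fw$S, e))  # SSE gradient wrt theta is -g
    if (max(abs(g)) < config$gradient_tolerance) {
      stop_reason <- "gradient_tolerance"; break
    }
    delta <- lm_step(fw$S, e, mu, n, p)
    cand <- unpack_params(model, theta + delta)
    fw_cand <- ann_forward(cand, X, jacobian = TRUE)
    sse_cand <- sum((y - fw_cand$scores)^2)
    accepted <- is.finite(sse_cand) && sse_cand < sse
    trace[[it]] <- data.frame(iteration = it, sse = sse, mu = mu,
                              sse_candidate = sse_cand,
                              accepted = accepted)
    if (accepted) {
      improved <- (sse - sse_cand) / n
      theta <- theta + delta
      model <- cand
      fw <- fw_cand
      e <- y - fw$scores
      sse <- sse_cand
      mu <- mu * config$mu_down
      if (improved < config$min_mse_delta) {
        stop_reason <- "min_mse_delta"; break
      }
    } else {
      mu <- mu * config$mu_up
    }
    if (mu < 1e-12) mu <- 1e-12
    if (mu > 1e12) { stop_reason <- "mu_overflow"; break }
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(iteration = integer(), sse = numeric(), mu = numeric(),
               sse_candidate = numeric(), accepted = logical())
  attr(model, "trace") <- trace
  attr(model, "stop_reason") <- stop_reason
  attr(model, "final_sse") <- sse
  model
}

# Solve (S'S + mu I) delta = S'e, using the dual (N x N) form when the
# parameter count exceeds the sample count.
#' @noRd
lm_step <- function(S, e, mu, n, p) {
  res <- tryCatch({
    if (p <= n) {
      A <- crossprod(S)
      diag(A) <- diag(A) + mu
      solve(A, drop(crossprod(S, e)))
    } else {
      A <- tcrossprod(S)
      diag(A) <- diag(A) + mu
      drop(crossprod(S, solve(A, e)))
    }
  }, error = function(err) err)
  if (inherits(res, "error"))
    np_stop("nirparity_singular_system",
            "damped normal equations are singular (mu = %.3g): %s",
            mu, conditionMessage(res))
  res
}

#' @noRd
design_matrix <- function(data, model = NULL) {
  X <- if (inherits(data, "encoded_dataset")) data$codes
  else if (inherits(data, "spectral_dataset")) data$absorbance
  else as.matrix(data)
  X <- unname(as.matrix(X))
  if (!is.null(model))
    np_assert(ncol(X) == model$input_dim, "nirparity_dim_mismatch",
              "data has %d features but the model expects %d",
              ncol(X), model$input_dim)
  X
}

#' Score and classify samples
#'
#' @param object a trained [ann_classifier()].
#' @param data an `encoded_dataset`, `spectral_dataset` or numeric
#'   matrix with the model's input dimension.
#' @param ... unused.
#' @return list with `scores` (in (0, 1) for the logistic model) and
#'   `labels` (1 iff score strictly exceeds the model threshold).
#' @export
predict.ann_classifier <- function(object, data, ...) {
  X <- design_matrix(data, object)
  s <- ann_forward(object, X)$scores
  list(scores = s, labels = as.integer(s > object$threshold))
}
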