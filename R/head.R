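#' Prediction-head parameters
#'
#' The head is a two-layer perceptron (hidden width `2d`, rectified-linear)
#' whose per-term logits are smoothed by one graph convolution over the
#' normalized label-space adjacency and re-mixed by a dense `gamma x gamma`
#' matrix before the logistic sigmoid:
#' `scores = sigmoid( (relu(X W1 + b1) W2 + b2) %*% A_hat %*% W_A )`.
#'
#' `W1`/`W2` use Kaiming-style initialization; `W_A` starts at the identity
#' plus small noise so early training approximates the graph-free baseline.
#'
#' @param d Input feature width.
#' @param gamma Number of retained GO terms.
#' @param seed Seed.
#' @return A `head_params` list (`W1`, `b1`, `W2`, `b2`, `W_A`).
#' @export
head_params <- function(d, gamma, seed = 0) {
  stopifnot(d >= 1, gamma >= 1)
  h <- 2L * d
  withr::with_seed(seed, {
    structure(list(
      W1 = matrix(rnorm(d * h, sd = sqrt(2 / d)), d, h),
      b1 = numeric(h),
      W2 = matrix(rnorm(h * gamma, sd = sqrt(2 / h)), h, gamma),
      b2 = numeric(gamma),
      W_A = diag(gamma) + matrix(rnorm(gamma * gamma, sd = 0.01),
                                 gamma, gamma)
    ), class = "head_params")
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Head forward pass
#'
#' @param x_mix A `b x d` batch of mixed protein features (a bare vector is
#'   treated as one row).
#' @param params [head_params()].
#' @param adjacency_hat `gamma x gamma` normalized adjacency (identity for
#'   the relation-off ablation).
#' @return A `b x gamma` score matrix with entries in `(0, 1)`.
#' @export
head_forward <- function(x_mix, params, adjacency_hat) {
  if (!is.matrix(x_mix)) x_mix <- matrix(x_mix, nrow = 1)
  if (ncol(x_mix) != nrow(params$W1)) {
    abort(paste0("x_mix width ", ncol(x_mix), " != W1 rows ",
                 nrow(params$W1)), class = "gofusion_shape_error")
  }
  gamma <- ncol(params$W2)
  if (!all(dim(adjacency_hat) == c(gamma, gamma))) {
    abort("adjacency_hat does not match gamma",
          class = "gofusion_shape_error")
  }
  H1 <- pmax(x_mix %*% params$W1 +
               rep(params$b1, each = nrow(x_mix)), 0)
  H <- H1 %*% params$W2 + rep(params$b2, each = nrow(x_mix))
  sigmoid((H %*% adjacency_hat) %*% params$W_A)
}

#' Training configuration
#'
#' The default recipe: Adam (`beta1` 0.9, `beta2` 0.999, `eps` 1e-9),
#' initial learning rate `2e-4` decayed by 0.6 every 5 epochs, 30 epochs of
#' binary cross-entropy with batch size 16. `variant = "small"` switches to
#' the `4e-5 / x0.5` schedule used for the largest upstream embedders.
#'
#' @param lr Initial learning rate.
#' @param decay Multiplicative decay factor.
#' @param decay_every Epoch period of the decay.
#' @param epochs Number of epochs.
#' @param batch_size Minibatch size.
#' @param seed Seed for shuffling, initialization and dropout.
#' @param variant `"default"` or `"small"`.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 2e-4, decay = 0.6, decay_every = 5,
                         epochs = 30, batch_size = 16, seed = 0,
                         variant = c("default", "small")) {
  variant <- match.arg(variant)
  if (variant == "small") {
    lr <- 4e-5
    decay <- 0.5
  }
  stopifnot(lr >= 0, epochs >= 1, batch_size >= 1)
  structure(list(lr = lr, decay = decay, decay_every = decay_every,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 beta1 = 0.9, beta2 = 0.999, eps = 1e-9,
                 seed = seed, variant = variant),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' `lr * decay ^ floor((epoch - 1) / decay_every)` for 1-based epochs.
#'
#' @param config [train_config()].
#' @param epoch 1-based epoch index.
#' @return Numeric learning rate.
#' @export
lr_at_epoch <- function(config, epoch) {
  config$lr * config$decay^((epoch - 1) %/% config$decay_every)
}

bce_loss <- function(scores, labels, eps = 1e-12) {
  p <- pmin(pmax(scores, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}
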