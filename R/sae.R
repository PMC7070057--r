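#' Sparse autoencoder configuration
#'
#' A single-hidden-layer autoencoder compresses variable-dimension raw
#' attributes (disease similarity rows, drug fingerprints) to a common
#' 64-dimensional code. The training objective has three terms: mean
#' half-squared reconstruction error, a KL-divergence penalty pulling the
#' mean activation of every hidden unit towards the sparsity target
#' `rho`, and an L2 weight-decay term.
#'
#' @param input_dim number of input features.
#' @param hidden_dim code size (default 64).
#' @param rho sparsity target in (0, 1); default 0.05.
#' @param alpha weight of the KL sparsity penalty; default 1.
#' @param beta weight-decay coefficient; default 1e-4.
#' @param epochs,batch_size,learning_rate mini-batch gradient-descent
#'   schedule (defaults 100 / 32 / 0.01).
#' @param seed integer seed for weight initialization and batch order.
#' @return an `sae_config` list.
#' @export
sae_config <- function(input_dim, hidden_dim = 64L, rho = 0.05, alpha = 1,
                       beta = 1e-4, epochs = 100L, batch_size = 32L,
                       learning_rate = 0.01, seed = 1L) {
  stopifnot(input_dim >= 1L, hidden_dim >= 1L, rho > 0, rho < 1,
            alpha >= 0, beta >= 0, epochs >= 1L, learning_rate > 0)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dim = as.integer(hidden_dim),
                 rho = rho, alpha = alpha, beta = beta,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "sae_config")
}

.sigmoid <- function(z) 1 / (1 + exp(-z))
.relu <- function(z) pmax(z, 0)

# forward pass; X is m x input_dim. Hidden activation is sigmoid so mean
# activations are rates in (0, 1) and the KL penalty is well defined;
# the output layer is ReLU.
.sae_forward <- function(model, X) {
  Zh <- sweep(X %*% model$W1, 2L, model$b1, `+`)
  H <- .sigmoid(Zh)
  Zo <- sweep(H %*% model$W2, 2L, model$b2, `+`)
  Xhat <- .relu(Zo)
  list(H = H, Zo = Zo, Xhat = Xhat)
}

#' KL sparsity penalty between a target and an observed activation rate
#'
#' `rho * log(rho/rho_hat) + (1-rho) * log((1-rho)/(1-rho_hat))`:
#' the KL divergence between two Bernoulli rates, non-negative and zero
#' iff the rates agree. Inputs are clamped to `[1e-8, 1 - 1e-8]`.
#'
#' @param rho sparsity target.
#' @param rho_hat observed mean activation (vectorized).
#' @return non-negative penalty, same length as `rho_hat`.
#' @export
kl_sparsity <- function(rho, rho_hat) {
  eps <- 1e-8
  rho <- min(max(rho, eps), 1 - eps)
  rho_hat <- pmin(pmax(rho_hat, eps), 1 - eps)
  rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat))
}

#' Sparse autoencoder loss
#'
#' Evaluates the three-term training objective on a batch:
#' `(1/m) * sum_i 0.5 * ||x_i - xhat_i||^2` (reconstruction), `alpha *
#' sum_j KL(rho || rho_hat_j)` with `rho_hat_j` the mean activation of
#' hidden unit `j` over the batch (sparsity), and `beta * ||W||_2^2` over
#' both weight matrices, biases excluded (decay).
#'
#' @param model an `sae_model` (see [train_sae()]).
#' @param X numeric matrix of raw vectors, one per row.
#' @param config the `sae_config`.
#' @return named numeric vector `c(total, reconstruction, sparsity,
#'   decay)`.
#' @export
sae_loss <- function(model, X, config) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 1L, all(is.finite(X)))
  fw <- .sae_forward(model, X)
  m <- nrow(X)
  recon <- sum((X - fw$Xhat)^2) / (2 * m)
  rho_hat <- colMeans(fw$H)
  if (any(rho_hat <= 0 | rho_hat >= 1)) {
    warning("mean hidden activation outside (0,1); clamped")
  }
  sparsity <- config$alpha * sum(kl_sparsity(config$rho, rho_hat))
  decay <- config$beta * (sum(model$W1^2) + sum(model$W2^2))
  total <- recon + sparsity + decay
  c(total = total, reconstruction = recon, sparsity = sparsity, decay = decay)
}

# analytic gradients of the full objective on a batch
.sae_gradient <- function(model, X, config) {
  m <- nrow(X)
  fw <- .sae_forward(model, X)
  eps <- 1e-8
  rho_hat <- pmin(pmax(colMeans(fw$H), eps), 1 - eps)
  rho <- min(max(config$rho, eps), 1 - eps)

  # output layer: d recon / d Zo; ReLU subgradient 0 at Zo <= 0
  d_out <- (fw$Xhat - X) * (fw$Zo > 0) / m
  gW2 <- crossprod(fw$H, d_out) + 2 * config$beta * model$W2
  gb2 <- colSums(d_out)

  # hidden layer: backprop + sparsity term through rho_hat = mean(H)
  kl_grad <- config$alpha * (-rho / rho_hat + (1 - rho) / (1 - rho_hat)) / m
  d_hidden <- (d_out %*% t(model$W2) +
                 matrix(kl_grad, m, length(kl_grad), byrow = TRUE)) *
    fw$H * (1 - fw$H)
  gW1 <- crossprod(X, d_hidden) + 2 * config$beta * model$W1
  gb1 <- colSums(d_hidden)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

#' Train a sparse autoencoder
#'
#' Mini-batch gradient descent on the three-term objective of
#' [sae_loss()]. Inputs are min-max scaled to [0, 1] per feature before
#' training (a no-op for similarity rows and bit vectors, which already
#' live there); the scaling is stored in the model and re-applied by
#' [sae_encode()]. Weights start from a seeded uniform
#' (-0.05, 0.05) draw; the decoder bias starts at the per-feature mean of
#' the scaled data so output units are live from the first epoch.
#'
#' @param X numeric matrix of raw vectors, one per row.
#' @param config an [sae_config()]; `config$input_dim` must equal
#'   `ncol(X)`.
#' @return an `sae_model`: weights (`W1`, `b1`, `W2`, `b2`), the config,
#'   the scaling (`scale_min`, `scale_range`) and a `loss_trajectory`
#'   data frame (epoch, total, reconstruction, sparsity, decay).
#' @export
train_sae <- function(X, config) {
  X <- as.matrix(X)
  if (ncol(X) != config$input_dim) {
    stop("ncol(X) = ", ncol(X), " != input_dim = ", config$input_dim)
  }
  stopifnot(all(is.finite(X)))
  scale_min <- apply(X, 2L, min)
  scale_range <- apply(X, 2L, max) - scale_min
  scale_range[scale_range == 0] <- 1
  Xs <- sweep(sweep(X, 2L, scale_min), 2L, scale_range, `/`)

  set.seed(config$seed)
  d <- config$input_dim; h <- config$hidden_dim
  model <- list(
    W1 = matrix(runif(d * h, -0.05, 0.05), d, h),
    b1 = rep(0, h),
    W2 = matrix(runif(h * d, -0.05, 0.05), h, d),
    b2 = colMeans(Xs),
    scale_min = scale_min, scale_range = scale_range,
    config = config
  )
  m <- nrow(Xs)
  bs <- min(config$batch_size, m)
  traj <- matrix(NA_real_, config$epochs, 4L)
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(m)
    starts <- seq(1L, m, by = bs)
    for (s in starts) {
      rows <- perm[s:min(s + bs - 1L, m)]
      g <- .sae_gradient(model, Xs[rows, , drop = FALSE], config)
      lr <- config$learning_rate
      model$W1 <- model$W1 - lr * g$W1
      model$b1 <- model$b1 - lr * g$b1
      model$W2 <- model$W2 - lr * g$W2
      model$b2 <- model$b2 - lr * g$b2
    }
    traj[ep, ] <- sae_loss(model, Xs, config)
    if (!all(is.finite(traj[ep, ]))) {
      stop("non-finite loss at epoch ", ep, "; lower the learning rate")
    }
  }
  model$loss_trajectory <- data.frame(
    epoch = seq_len(config$epochs),
    total = traj[, 1L], reconstruction = traj[, 2L],
    sparsity = traj[, 3L], decay = traj[, 4L]
  )
  class(model) <- "sae_model"
  model
}

#' Encode raw vectors with a trained sparse autoencoder
#'
#' Applies the stored min-max scaling and the encoder half of the model.
#' A pure function: the same input always yields the same code.
#'
#' @param model a trained `sae_model`.
#' @param X matrix (or single vector) with `input_dim` columns.
#' @return matrix of codes, `hidden_dim` columns, one row per input row.
#' @export
sae_encode <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != model$config$input_dim) {
    stop("input has ", ncol(X), " columns; model expects ",
         model$config$input_dim)
  }
  Xs <- sweep(sweep(X, 2L, model$scale_min), 2L, model$scale_range, `/`)
  H <- .sigmoid(sweep(Xs %*% model$W1, 2L, model$b1, `+`))
  rownames(H) <- rownames(X)
  H
}
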