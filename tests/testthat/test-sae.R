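# build an autoencoder with explicit weights, bypassing training
manual_sae <- function(W1, b1, W2, b2, config) {
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 scale_min = rep(0, config$input_dim),
                 scale_range = rep(1, config$input_dim),
                 config = config),
            class = "sae_model")
}

test_that("KL sparsity penalty matches the Bernoulli-divergence formula", {
  expect_equal(kl_sparsity(0.05, 0.05), 0)
  expect_equal(kl_sparsity(0.05, 0.5),
               0.05 * log(0.05 / 0.5) + 0.95 * log(0.95 / 0.5))
  expect_equal(kl_sparsity(0.05, 0.5), 0.4946, tolerance = 1e-4)
  # non-negative over a grid (Gibbs inequality)
  grid <- expand.grid(rho = seq(0.05, 0.95, by = 0.1),
                      rho_hat = seq(0.05, 0.95, by = 0.1))
  expect_true(all(mapply(kl_sparsity, grid$rho, grid$rho_hat) >= 0))
  # boundary inputs are clamped, not NaN
  expect_true(is.finite(kl_sparsity(0.05, 0)))
  expect_true(is.finite(kl_sparsity(0.05, 1)))
})

test_that("loss decomposes into reconstruction, sparsity and decay terms", {
  cfg <- sae_config(input_dim = 2, hidden_dim = 3, alpha = 0, beta = 0)
  # zero decoder: xhat = relu(0) = 0 whatever the input
  m <- manual_sae(W1 = matrix(0.1, 2, 3), b1 = rep(0, 3),
                  W2 = matrix(0, 3, 2), b2 = rep(0, 2), cfg)
  l <- sae_loss(m, matrix(c(1, 0), 1, 2), cfg)
  expect_equal(unname(l["total"]), 0.5)           # (1/m) * 0.5 * ||x||^2
  expect_equal(unname(l["sparsity"]), 0)
  expect_equal(unname(l["decay"]), 0)

  # alpha, beta > 0 add exactly the formula terms
  cfg2 <- sae_config(input_dim = 2, hidden_dim = 3, alpha = 2, beta = 0.5,
                     rho = 0.2)
  l2 <- sae_loss(m, matrix(c(1, 0), 1, 2), cfg2)
  H <- 1 / (1 + exp(-(c(1, 0) %*% m$W1)))
  expect_equal(unname(l2["sparsity"]),
               2 * sum(sapply(H, function(r) kl_sparsity(0.2, r))))
  expect_equal(unname(l2["decay"]), 0.5 * (sum(m$W1^2) + sum(m$W2^2)))
  expect_equal(unname(l2["total"]), unname(sum(l2[-1])))
})

test_that("analytic gradients match central finite differences", {
  set.seed(4)
  cfg <- sae_config(input_dim = 3, hidden_dim = 4, rho = 0.1, alpha = 0.7,
                    beta = 0.01)
  X <- matrix(runif(5 * 3), 5, 3)
  m <- manual_sae(W1 = matrix(runif(12, -0.3, 0.3), 3, 4),
                  b1 = runif(4, -0.1, 0.1),
                  W2 = matrix(runif(12, -0.3, 0.3), 4, 2 + 1),
                  b2 = runif(3, 0.5, 0.8), cfg)
  # keep output pre-activations away from the ReLU kink
  fw <- hetlink:::.sae_forward(m, X)
  expect_gt(min(fw$Zo), 0.05)

  g <- hetlink:::.sae_gradient(m, X, cfg)
  h <- 1e-6
  for (par in c("W1", "b1", "W2", "b2")) {
    num <- m[[par]]
    for (i in seq_along(num)) {
      mp <- m; mp[[par]][i] <- mp[[par]][i] + h
      mm <- m; mm[[par]][i] <- mm[[par]][i] - h
      num[i] <- (sae_loss(mp, X, cfg)["total"] -
                   sae_loss(mm, X, cfg)["total"]) / (2 * h)
    }
    expect_equal(as.numeric(g[[par]]), as.numeric(num), tolerance = 1e-5)
  }
})

test_that("training reconstructs constant data and is reproducible", {
  set.seed(9)
  x0 <- runif(10)
  X <- matrix(rep(x0, each = 50), 50, 10)
  cfg <- sae_config(input_dim = 10, hidden_dim = 6, alpha = 0, beta = 0,
                    epochs = 200, learning_rate = 0.05, seed = 2)
  m <- train_sae(X, cfg)
  expect_lt(tail(m$loss_trajectory$reconstruction, 1), 1e-3)
  expect_lte(tail(m$loss_trajectory$total, 1), m$loss_trajectory$total[1])

  m2 <- train_sae(X, cfg)
  expect_identical(m$W1, m2$W1)
  expect_identical(m$W2, m2$W2)
})

test_that("an over-complete autoencoder drives reconstruction loss to ~0", {
  set.seed(12)
  X <- matrix(runif(10 * 4), 10, 4)
  cfg <- sae_config(input_dim = 4, hidden_dim = 8, alpha = 0, beta = 0,
                    epochs = 5000, learning_rate = 0.3, batch_size = 10,
                    seed = 5)
  m <- train_sae(X, cfg)
  expect_lt(tail(m$loss_trajectory$reconstruction, 1), 1e-3)
})

test_that("loss trajectory is non-increasing at a small learning rate", {
  set.seed(21)
  X <- matrix(runif(30 * 6), 30, 6)
  cfg <- sae_config(input_dim = 6, hidden_dim = 4, epochs = 50,
                    learning_rate = 0.001, batch_size = 30, seed = 3)
  m <- train_sae(X, cfg)
  expect_true(all(diff(m$loss_trajectory$total) <= 1e-6))
})

test_that("stronger sparsity pressure lowers mean hidden activation", {
  set.seed(30)
  X <- matrix(runif(40 * 8), 40, 8)
  act <- vapply(c(0, 10), function(a) {
    cfg <- sae_config(input_dim = 8, hidden_dim = 5, alpha = a, beta = 0,
                      rho = 0.05, epochs = 150, seed = 4)
    mean(sae_encode(train_sae(X, cfg), X))
  }, 0)
  expect_lte(act[2], act[1])
})

test_that("encoding is pure, 64-dimensional by default, and checks dimensions", {
  set.seed(2)
  X <- matrix(runif(70 * 20), 70, 20)
  m <- train_sae(X, sae_config(input_dim = 20, epochs = 10, seed = 1))
  H <- sae_encode(m, X)
  expect_equal(ncol(H), 64L)
  expect_identical(H, sae_encode(m, X))
  expect_true(all(is.finite(sae_encode(m, rep(0, 20)))))
  expect_error(sae_encode(m, matrix(0, 2, 5)), "columns")
  expect_error(train_sae(X, sae_config(input_dim = 7)), "input_dim")
})
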