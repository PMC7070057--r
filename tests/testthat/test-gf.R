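edge_df <- function(i, j, y = NULL) {
  d <- data.frame(head_index = i, tail_index = j)
  if (!is.null(y)) d$y <- y
  d
}

test_that("factorization loss matches direct arithmetic", {
  Z <- rbind(c(1, 0), c(0, 1))
  e <- edge_df(0L, 1L)
  expect_equal(gf_loss(e, Z, lambda = 0), 0.5)          # 0.5 * (1 - 0)^2
  expect_equal(gf_loss(e, Z, lambda = 2), 0.5 + (2 / 2) * 2)
  # perfect reconstruction gives zero loss
  Zp <- rbind(c(1, 0), c(1, 0))
  expect_equal(gf_loss(e, Zp, lambda = 0), 0)
})

test_that("per-node gradient matches the closed form and finite differences", {
  Z <- rbind(c(1, 0), c(0, 1))
  e <- edge_df(0L, 1L)
  expect_equal(gf_gradient(e, Z, node = 0L, lambda = 0), c(0, -1))
  # isolated node: only the regularizer
  Z3 <- rbind(Z, c(2, 3))
  expect_equal(gf_gradient(e, Z3, node = 2L, lambda = 0), c(0, 0))
  expect_equal(gf_gradient(e, Z3, node = 2L, lambda = 0.5), 0.5 * c(2, 3))

  # finite-difference oracle on random graphs of up to 6 nodes
  set.seed(14)
  for (rep in 1:8) {
    n <- sample(3:6, 1)
    pairs <- t(combn(0:(n - 1), 2))
    keep <- runif(nrow(pairs)) < 0.6
    if (!any(keep)) next
    e <- edge_df(pairs[keep, 1], pairs[keep, 2])
    Zr <- matrix(rnorm(n * 3), n, 3)
    lam <- runif(1, 0, 0.5)
    h <- 1e-6
    for (node in 0:(n - 1)) {
      g <- gf_gradient(e, Zr, node, lam)
      num <- numeric(3)
      for (c_ in 1:3) {
        Zp <- Zr; Zp[node + 1, c_] <- Zp[node + 1, c_] + h
        Zm <- Zr; Zm[node + 1, c_] <- Zm[node + 1, c_] - h
        num[c_] <- (gf_loss(e, Zp, lam) - gf_loss(e, Zm, lam)) / (2 * h)
      }
      expect_equal(g, num, tolerance = 1e-6)
    }
  }
})

test_that("one SGD step applies the printed update symmetrically", {
  Z <- rbind(c(1, 0), c(0, 1))
  Z1 <- gf_sgd_step(Z, 0L, 1L, y = 1, eta = 1, lambda = 0)
  expect_equal(Z1[1, ], c(1, 1))   # Z_i + eta * res * Z_j
  expect_equal(Z1[2, ], c(1, 1))   # uses the pre-step Z_i

  # zero residual, no regularization: nothing moves
  Zp <- rbind(c(1, 0), c(1, 0))
  expect_equal(gf_sgd_step(Zp, 0L, 1L, y = 1, eta = 0.5, lambda = 0), Zp)

  # zero residual with lambda > 0 shrinks rows towards the origin,
  # decreasing the regularized loss
  Zs <- gf_sgd_step(Zp, 0L, 1L, y = 1, eta = 0.5, lambda = 0.1)
  expect_true(all(abs(Zs) <= abs(Zp)))
  e <- edge_df(0L, 1L)
  expect_lt(gf_loss(e, Zs, 0.1) - 0.5 * (1 - sum(Zs[1, ] * Zs[2, ]))^2,
            gf_loss(e, Zp, 0.1) - 0)
})

test_that("a single edge converges to unit inner product", {
  e2 <- data.frame(head_id = "p1", tail_id = "p2",
                   relation_type = "protein-protein")
  emb <- gf_factorize(assoc_network(e2), gf_config(rank = 2, lambda = 1e-4,
                                                   seed = 3))
  expect_gt(sum(emb$Z[1, ] * emb$Z[2, ]), 0.9)
  expect_lt(sum(emb$Z[1, ] * emb$Z[2, ]), 1.1)
})

test_that("factorization is deterministic and ignores appended isolated nodes", {
  tri <- data.frame(head_id = c("p1", "p2", "p3"),
                    tail_id = c("p2", "p3", "p1"),
                    relation_type = "protein-protein")
  net <- assoc_network(tri)
  cfg <- gf_config(rank = 4, max_epochs = 30, seed = 5)
  z1 <- gf_factorize(net, cfg)$Z
  expect_identical(z1, gf_factorize(net, cfg)$Z)

  net_iso <- assoc_network(tri, nodes = data.frame(
    node_id = c("p8", "p9"), node_type = "protein"))
  z2 <- gf_factorize(net_iso, cfg)$Z
  expect_identical(z1, z2[rownames(z1), ])
})

test_that("training loss decreases and the log records every sweep", {
  ds <- small_dataset()
  emb <- gf_factorize(ds$network, gf_config(rank = 8, max_epochs = 40,
                                            seed = 2))
  expect_lt(tail(emb$log$loss, 1), emb$log$loss[1])
  expect_equal(emb$log$epoch, seq_len(nrow(emb$log)))
  expect_true(all(is.finite(emb$Z)))
})

test_that("a planted rank-2 graph is reconstructed with high AUC", {
  set.seed(8)
  n <- 20
  U <- matrix(rnorm(n * 2), n, 2)
  ids <- sprintf("p%02d", 1:n)
  pairs <- t(combn(1:n, 2))
  linked <- rowSums(U[pairs[, 1], ] * U[pairs[, 2], ]) > 0
  e <- data.frame(head_id = ids[pairs[linked, 1]],
                  tail_id = ids[pairs[linked, 2]],
                  relation_type = "protein-protein")
  net <- assoc_network(e, nodes = data.frame(node_id = ids,
                                             node_type = "protein"))
  emb <- gf_factorize(net, gf_config(rank = 8, lambda = 1e-3, epsilon = 1e-6, seed = 1))
  Z <- emb$Z[ids, ]
  ip <- rowSums(Z[pairs[, 1], ] * Z[pairs[, 2], ])
  expect_gte(roc_pr_curves(as.integer(linked), ip)$auc, 0.95)
})

test_that("embeddings round-trip through the TSV format", {
  tri <- data.frame(head_id = c("p1", "p2", "p3"),
                    tail_id = c("p2", "p3", "p1"),
                    relation_type = "protein-protein")
  emb <- gf_factorize(assoc_network(tri), gf_config(rank = 4, max_epochs = 10,
                                                    seed = 1))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_embedding(emb, f)
  Z <- read_embedding(f)
  expect_equal(Z, emb$Z, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(rownames(Z), rownames(emb$Z))
})
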