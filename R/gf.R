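#' Graph factorization configuration
#'
#' Behavior vectors are learned by factorizing the network adjacency
#' matrix: minimize
#' `f = 1/2 * sum_{(i,j) in E} (Y_ij - <Z_i,Z_j>)^2 +
#'  lambda/2 * sum_i ||Z_i||^2`
#' over the factor matrix `Z` (one row per node) by sequential stochastic
#' gradient descent with learning rate `1/sqrt(t)` under a global step
#' counter `t`, stopping when the squared Frobenius change of `Z` between
#' sweeps drops to `epsilon` or after `max_epochs` sweeps. Runtime is
#' linear in the number of edges per sweep.
#'
#' @param rank embedding dimension `r` (default 64).
#' @param lambda L2 regularization weight (default 0.01).
#' @param epsilon convergence threshold on `||Z - Z'||_F^2` between
#'   sweeps (default 1e-4).
#' @param max_epochs sweep cap (default 500; the `1/sqrt(t)` schedule
#'   makes late sweeps cheap corrections, and the Frobenius test usually
#'   stops the run well before the cap).
#' @param seed integer seed for the initialization and the per-sweep edge
#'   shuffles.
#' @return a `gf_config` list.
#' @export
gf_config <- function(rank = 64L, lambda = 0.01, epsilon = 1e-4,
                      max_epochs = 500L, seed = 1L) {
  stopifnot(rank >= 1L, lambda >= 0, epsilon > 0, max_epochs >= 1L)
  structure(list(rank = as.integer(rank), lambda = lambda, epsilon = epsilon,
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed)),
            class = "gf_config")
}

#' Graph factorization loss
#'
#' Evaluates the regularized squared reconstruction error of an embedding
#' against the (unweighted) positive edge set; each undirected edge is
#' counted once.
#'
#' @param edges data frame with `head_index`, `tail_index` (0-based) and
#'   optionally a weight column `y` (defaults to 1).
#' @param Z numeric matrix, one row per node (row `i+1` is node with
#'   global index `i`).
#' @param lambda regularization weight.
#' @return scalar loss.
#' @export
gf_loss <- function(edges, Z, lambda) {
  y <- if (!is.null(edges$y)) edges$y else rep(1, nrow(edges))
  ip <- rowSums(Z[edges$head_index + 1L, , drop = FALSE] *
                  Z[edges$tail_index + 1L, , drop = FALSE])
  0.5 * sum((y - ip)^2) + lambda / 2 * sum(Z^2)
}

#' Gradient of the factorization loss for one node
#'
#' `-sum_{j in N(i)} (Y_ij - <Z_i,Z_j>) Z_j + lambda * Z_i`, where `N(i)`
#' are the node's neighbors in the edge set.
#'
#' @param edges as in [gf_loss()].
#' @param Z embedding matrix.
#' @param node 0-based global index of the node.
#' @param lambda regularization weight.
#' @return gradient vector of length `ncol(Z)`.
#' @export
gf_gradient <- function(edges, Z, node, lambda) {
  inc <- edges$head_index == node | edges$tail_index == node
  g <- lambda * Z[node + 1L, ]
  if (any(inc)) {
    nbr <- ifelse(edges$head_index[inc] == node,
                  edges$tail_index[inc], edges$head_index[inc])
    y <- if (!is.null(edges$y)) edges$y[inc] else rep(1, sum(inc))
    Zn <- Z[nbr + 1L, , drop = FALSE]
    res <- y - as.numeric(Zn %*% Z[node + 1L, ])
    g <- g - colSums(res * Zn)
  }
  g
}

#' One stochastic gradient step on an edge
#'
#' Applies the per-edge descent update
#' `Z_i <- Z_i + eta * ((Y_ij - <Z_i,Z_j>) Z_j - lambda * Z_i)` to both
#' endpoint rows (the second row update uses the pre-step value of the
#' first, keeping the update symmetric in the endpoints).
#'
#' @param Z embedding matrix (copied, not modified in place).
#' @param i,j 0-based endpoint indices.
#' @param y edge weight (1 for an unweighted edge).
#' @param eta learning rate.
#' @param lambda regularization weight.
#' @return updated copy of `Z`.
#' @export
gf_sgd_step <- function(Z, i, j, y = 1, eta, lambda) {
  stopifnot(eta > 0)
  zi <- Z[i + 1L, ]; zj <- Z[j + 1L, ]
  res <- y - sum(zi * zj)
  Z[i + 1L, ] <- zi + eta * (res * zj - lambda * zi)
  Z[j + 1L, ] <- zj + eta * (res * zi - lambda * zj)
  if (!all(is.finite(Z[c(i, j) + 1L, ]))) stop("non-finite SGD update")
  Z
}

#' Learn behavior vectors by adjacency factorization
#'
#' Runs sequential SGD over the training edge set (the caller must strip
#' any held-out edges first: the embedding sees only the network it is
#' given). The factor matrix is initialized from a seeded uniform draw on
#' `(-0.5/sqrt(r), 0.5/sqrt(r))`; each sweep visits the edges in a fresh
#' seeded shuffle; the learning rate is `1/sqrt(t)` with `t` advancing
#' once per edge visit across the whole run. Training stops when the
#' squared Frobenius change between consecutive sweeps is at most
#' `epsilon`, and aborts if the loss exceeds ten times its initial value.
#'
#' Isolated nodes keep their initialization: every node of the graph has
#' a behavior row whether or not it has training edges.
#'
#' @param network an `assoc_network` containing the training edges.
#' @param config a [gf_config()].
#' @return a `gf_embedding`: list with `Z` (n x rank matrix, rownames =
#'   node ids in global-index order), `config`, and `log` (data frame
#'   `epoch`, `loss`, `frob_change`) plus a `converged` flag.
#' @export
gf_factorize <- function(network, config = gf_config()) {
  edges <- network$edges
  if (nrow(edges) == 0L) stop("cannot factorize a network with no edges")
  n <- nrow(network$nodes)
  r <- config$rank
  # row-wise seeded init: a node's starting row depends only on (seed,
  # row index), so appending isolated nodes to a graph leaves the
  # existing nodes' trajectories untouched
  Z <- matrix(0, n, r)
  for (i in seq_len(n)) {
    set.seed(as.integer((as.numeric(config$seed) + i * 2654435761) %% 2147483647))
    Z[i, ] <- runif(r, -0.5 / sqrt(r), 0.5 / sqrt(r))
  }
  y <- rep(1, nrow(edges))
  loss0 <- gf_loss(edges, Z, config$lambda)
  t <- 1
  log_rows <- vector("list", config$max_epochs)
  converged <- FALSE
  epochs_run <- 0L
  for (ep in seq_len(config$max_epochs)) {
    Zprev <- Z
    set.seed(derive_seed(config$seed, paste0("sweep", ep)))
    ord <- sample.int(nrow(edges))
    sweep_out <- gf_epoch_sweep(Z, edges$head_index[ord],
                                edges$tail_index[ord], y[ord],
                                config$lambda, t)
    Z <- sweep_out$Z
    t <- sweep_out$t
    if (t < 0) stop("non-finite embedding update; reduce lambda or rank")
    loss <- gf_loss(edges, Z, config$lambda)
    if (!is.finite(loss) || loss > 10 * loss0) {
      stop("factorization diverged at sweep ", ep, " (loss ", signif(loss, 4),
           " vs initial ", signif(loss0, 4), ")")
    }
    frob <- sum((Z - Zprev)^2)
    log_rows[[ep]] <- data.frame(epoch = ep, loss = loss, frob_change = frob)
    epochs_run <- ep
    if (frob <= config$epsilon) { converged <- TRUE; break }
  }
  rownames(Z) <- network$nodes$node_id[order(network$nodes$global_index)]
  structure(list(Z = Z, config = config,
                 log = do.call(rbind, log_rows[seq_len(epochs_run)]),
                 converged = converged),
            class = "gf_embedding")
}

#' Write / read an embedding as TSV
#'
#' One row per node: `node_id` followed by the `rank` coordinates.
#'
#' @param embedding a `gf_embedding` (or any matrix with rownames).
#' @param path file path.
#' @export
write_embedding <- function(embedding, path) {
  Z <- if (inherits(embedding, "gf_embedding")) embedding$Z else embedding
  df <- data.frame(node_id = rownames(Z), Z, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = c("node_id", paste0("v", seq_len(ncol(Z)))))
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  Z <- as.matrix(df[, -1L, drop = FALSE])
  rownames(Z) <- df[[1L]]
  Z
}
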