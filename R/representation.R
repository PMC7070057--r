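#' Assemble node representations
#'
#' A node's full representation concatenates its 64-dimensional attribute
#' vector (sequence composition, disease semantics or fingerprint code)
#' with its 64-dimensional behavior vector (the graph-factorization row),
#' attribute first. Single-source modes keep just one half; the halves of
#' the combined vector always equal the single-mode vectors exactly.
#'
#' @param network an `assoc_network`.
#' @param attributes numeric matrix of attribute vectors, rownames = node
#'   ids.
#' @param embedding a `gf_embedding` (or matrix with node-id rownames).
#' @param mode `"both"` (default), `"attribute"` or `"behavior"`.
#' @return numeric matrix, one row per node in global-index order;
#'   128 columns for `"both"`, 64 for the single modes.
#' @export
node_representations <- function(network, attributes = NULL, embedding = NULL,
                                 mode = c("both", "attribute", "behavior")) {
  mode <- match.arg(mode)
  ids <- network$nodes$node_id[order(network$nodes$global_index)]
  pick <- function(M, what) {
    if (is.null(M)) stop(what, " matrix required for mode '", mode, "'")
    if (inherits(M, "gf_embedding")) M <- M$Z
    missing <- setdiff(ids, rownames(M))
    if (length(missing)) {
      miss_t <- network$nodes$node_type[match(missing, network$nodes$node_id)]
      stop("missing ", what, " for node(s): ",
           paste(head(paste0(missing, " (", miss_t, ")"), 5L), collapse = ", "))
    }
    M[ids, , drop = FALSE]
  }
  R <- switch(mode,
    attribute = pick(attributes, "attribute"),
    behavior = pick(embedding, "behavior"),
    both = cbind(pick(attributes, "attribute"), pick(embedding, "behavior"))
  )
  colnames(R) <- switch(mode,
    attribute = paste0("a", seq_len(ncol(R))),
    behavior = paste0("b", seq_len(ncol(R))),
    both = c(paste0("a", seq_len(ncol(R) / 2)), paste0("b", seq_len(ncol(R) / 2)))
  )
  R
}

#' Feature vector of a candidate node pair
#'
#' Concatenates the two endpoint representations in canonical order
#' (lower global index first), so an undirected pair always maps to the
#' same vector regardless of the order the endpoints are supplied in.
#'
#' @param pairs data frame with `head_index`, `tail_index` (0-based
#'   global indices; any order).
#' @param representations matrix from [node_representations()] (rows in
#'   global-index order).
#' @return numeric matrix, one row per pair, `2 * ncol(representations)`
#'   columns.
#' @export
pair_features <- function(pairs, representations) {
  lo <- pmin(pairs$head_index, pairs$tail_index)
  hi <- pmax(pairs$head_index, pairs$tail_index)
  X <- cbind(representations[lo + 1L, , drop = FALSE],
             representations[hi + 1L, , drop = FALSE])
  colnames(X) <- c(paste0("h.", colnames(representations)),
                   paste0("t.", colnames(representations)))
  rownames(X) <- NULL
  X
}

#' Link classifier specification
#'
#' Four classifier families are supported for scoring candidate edges:
#' random forest (`"rf"`, the default), extremely randomized trees
#' (`"et"`), L2-regularized logistic regression (`"lr"`) and Gaussian
#' naive Bayes (`"nb"`). The ensemble models use 100 trees with Gini
#' impurity and unlimited depth; the logistic model uses a ridge penalty
#' with strength `1/n`; all are pinned explicitly rather than delegated
#' to a library's defaults.
#'
#' @param kind one of `"rf"`, `"et"`, `"lr"`, `"nb"`.
#' @param num_trees trees for the ensemble kinds.
#' @param seed integer seed.
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("rf", "et", "lr", "nb"),
                            num_trees = 100L, seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, num_trees = as.integer(num_trees),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Train a link classifier
#'
#' @param X feature matrix from [pair_features()].
#' @param labels 0/1 vector (both classes must be present).
#' @param spec a [classifier_spec()].
#' @return a `link_classifier` holding the fitted model and the spec.
#' @export
train_classifier <- function(X, labels, spec = classifier_spec()) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("training data must contain both classes")
  }
  stopifnot(nrow(X) == length(labels))
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  fit <- switch(spec$kind,
    rf = ranger::ranger(
      x = X, y = factor(labels, levels = c(0L, 1L)),
      num.trees = spec$num_trees, splitrule = "gini",
      probability = TRUE, seed = spec$seed, num.threads = 1L),
    et = ranger::ranger(
      x = X, y = factor(labels, levels = c(0L, 1L)),
      num.trees = spec$num_trees, splitrule = "extratrees",
      num.random.splits = 1L, replace = FALSE, sample.fraction = 1,
      probability = TRUE, seed = spec$seed, num.threads = 1L),
    lr = glmnet::glmnet(
      x = X, y = labels, family = "binomial", alpha = 0,
      lambda = 1 / length(labels), standardize = TRUE),
    nb = e1071::naiveBayes(x = as.data.frame(X), y = factor(labels))
  )
  structure(list(fit = fit, spec = spec, n_features = ncol(X),
                 feature_names = colnames(X)),
            class = "link_classifier")
}

#' Score candidate pairs
#'
#' @param model a trained `link_classifier`.
#' @param X feature matrix with the training feature dimension.
#' @return numeric vector of probabilities in [0, 1] that each pair is a
#'   true association.
#' @export
predict_scores <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != model$n_features) {
    stop("feature dimension ", ncol(X), " != training dimension ",
         model$n_features)
  }
  colnames(X) <- model$feature_names
  p <- switch(model$spec$kind,
    rf = ,
    et = predict(model$fit, data = X, num.threads = 1L)$predictions[, "1"],
    lr = as.numeric(predict(model$fit, newx = X, type = "response",
                            s = model$fit$lambda[length(model$fit$lambda)])),
    nb = predict(model$fit, newdata = as.data.frame(X), type = "raw")[, "1"]
  )
  unname(pmin(pmax(p, 0), 1))
}

#' Rank candidate partners of an anchor node
#'
#' Scores every type-legal (anchor, candidate) pair and returns the
#' candidates in descending score order, ties broken by candidate id so
#' rankings are stable across runs.
#'
#' @param model a trained `link_classifier`.
#' @param network an `assoc_network`.
#' @param anchor_id node id of the anchor.
#' @param candidate_ids character vector of candidate node ids; defaults
#'   to all nodes whose type forms a legal relation with the anchor's
#'   type (excluding the anchor itself).
#' @param representations matrix from [node_representations()].
#' @return data frame `candidate`, `score`, sorted descending.
#' @export
rank_candidates <- function(model, network, anchor_id, candidate_ids = NULL,
                            representations) {
  nodes <- network$nodes
  a <- match(anchor_id, nodes$node_id)
  if (is.na(a)) stop("unknown anchor node: ", anchor_id)
  a_type <- nodes$node_type[a]
  rel <- relation_types()
  legal_types <- unique(c(rel$type_b[rel$type_a == a_type],
                          rel$type_a[rel$type_b == a_type]))
  if (is.null(candidate_ids)) {
    candidate_ids <- nodes$node_id[nodes$node_type %in% legal_types &
                                     nodes$node_id != anchor_id]
  } else {
    c_types <- nodes$node_type[match(candidate_ids, nodes$node_id)]
    if (anyNA(c_types)) stop("unknown candidate node(s)")
    if (!all(c_types %in% legal_types)) {
      stop("candidate type(s) not legal for anchor type ", a_type)
    }
  }
  if (length(candidate_ids) == 0L) {
    warning("no legal candidates for ", anchor_id)
    return(data.frame(candidate = character(0), score = numeric(0)))
  }
  pairs <- data.frame(
    head_index = nodes$global_index[a],
    tail_index = nodes$global_index[match(candidate_ids, nodes$node_id)]
  )
  sc <- predict_scores(model, pair_features(pairs, representations))
  out <- data.frame(candidate = candidate_ids, score = sc,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$candidate, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
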