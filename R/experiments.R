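# one row of evaluation metrics from labels + scores
.metric_row <- function(labels, scores) {
  cm <- confusion_metrics(labels, scores)
  rc <- roc_pr_curves(labels, scores)
  data.frame(accuracy = cm$accuracy, sensitivity = cm$sensitivity,
             specificity = cm$specificity, precision = cm$precision,
             mcc = cm$mcc, auc = rc$auc, aupr = rc$aupr)
}

.metric_cols <- c("accuracy", "sensitivity", "specificity", "precision",
                  "mcc", "auc", "aupr")

# mean +/- sd summary over the metric columns of a per-fold table
.summarize_folds <- function(per_fold, by = NULL) {
  if (is.null(by)) {
    data.frame(t(colMeans(per_fold[.metric_cols])),
               t(setNames(apply(per_fold[.metric_cols], 2L, sd),
                          paste0(.metric_cols, "_sd"))))
  } else {
    do.call(rbind, lapply(split(per_fold, per_fold[[by]]), function(d) {
      cbind(d[1L, by, drop = FALSE], .summarize_folds(d), row.names = NULL)
    }))
  }
}

#' Build the balanced labeled edge set of a network
#'
#' Positive examples are the known relationships; an equal number of
#' unconfirmed relationships is drawn by stratified negative sampling
#' ([sample_negatives()]).
#'
#' @param network an `assoc_network`.
#' @param seed integer seed for the negative draw.
#' @return data frame of labeled edges (`label` 1/0) with `pos_row`
#'   giving, for positives, the row in `network$edges`.
#' @export
labeled_edge_set <- function(network, seed) {
  pos <- network$edges
  pos$label <- 1
  pos$pos_row <- seq_len(nrow(pos))
  neg <- sample_negatives(network, count = nrow(pos),
                          seed = derive_seed(seed, "negatives"))
  neg$pos_row <- NA_integer_
  rbind(pos, neg)
}

# Shared cross-validation engine. For each fold the behavior embedding is
# re-fit on the training positives only (the tested links are stripped
# before factorization; this is asserted, not assumed), then every
# requested representation mode x classifier kind is trained on the
# training pairs and scored on the test pairs.
.cv_engine <- function(network, attributes, labeled, fold, modes, kinds,
                       gf = gf_config(), seed = 1L, need_gf = TRUE) {
  k <- max(fold) + 1L
  rows <- list()
  for (f in seq_len(k) - 1L) {
    tr <- labeled[fold != f, , drop = FALSE]
    te <- labeled[fold == f, , drop = FALSE]
    emb <- NULL
    if (need_gf) {
      gf_net <- .edge_subset_network(network, tr$pos_row[tr$label == 1])
      test_keys <- paste(te$head_index[te$label == 1],
                         te$tail_index[te$label == 1])
      if (length(intersect(test_keys, .pair_keys(gf_net)))) {
        stop("leakage: test edges present in the embedding training graph")
      }
      cfg <- gf
      cfg$seed <- derive_seed(seed, paste0("gf_fold", f))
      emb <- gf_factorize(gf_net, cfg)
    }
    for (mode in modes) {
      reps <- node_representations(network, attributes, emb, mode)
      Xtr <- pair_features(tr, reps)
      Xte <- pair_features(te, reps)
      for (kind in kinds) {
        model <- train_classifier(Xtr, tr$label,
                                  classifier_spec(kind,
                                                  seed = derive_seed(seed, "clf")))
        sc <- predict_scores(model, Xte)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(fold = f, mode = mode, classifier = kind),
          .metric_row(te$label, sc))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' k-fold cross-validated link prediction
#'
#' The paper-style protocol: balance the known relationships with
#' sampled negatives, split into `k` mutually exclusive folds, and for
#' each fold re-fit the behavior embedding on the training positives
#' only, train the classifier on the training pairs and score the test
#' pairs.
#'
#' @param network an `assoc_network`.
#' @param attributes attribute matrix from [compute_attributes()]
#'   (`$attributes`); may be NULL for `mode = "behavior"`.
#' @param k number of folds (default 5).
#' @param mode representation mode (`"both"`, `"attribute"`,
#'   `"behavior"`).
#' @param classifier classifier kind (`"rf"`, `"et"`, `"lr"`, `"nb"`).
#' @param gf a [gf_config()] (its seed is re-derived per fold).
#' @param seed master seed for negative sampling, folds, embeddings and
#'   the classifier.
#' @return list with `per_fold` (one metrics row per fold) and `summary`
#'   (mean and sd of each metric).
#' @export
cross_validate <- function(network, attributes = NULL, k = 5L, mode = "both",
                           classifier = "rf", gf = gf_config(), seed = 1L) {
  labeled <- labeled_edge_set(network, seed)
  fold <- split_folds(labeled, k, derive_seed(seed, "folds"))
  per_fold <- .cv_engine(network, attributes, labeled, fold, modes = mode,
                         kinds = classifier, gf = gf, seed = seed,
                         need_gf = mode != "attribute")
  list(per_fold = per_fold, summary = .summarize_folds(per_fold))
}

#' Feature ablation: attribute vs behavior vs combined
#'
#' Runs the cross-validation protocol for the three representation modes
#' with identical negative samples, fold assignments and per-fold
#' embeddings, so rows differ only in the features handed to the
#' classifier.
#'
#' @inheritParams cross_validate
#' @return list with `per_fold` (fold x mode metrics) and `summary` (one
#'   row per mode).
#' @export
ablation_experiment <- function(network, attributes, k = 5L, classifier = "rf",
                                gf = gf_config(), seed = 1L) {
  labeled <- labeled_edge_set(network, seed)
  fold <- split_folds(labeled, k, derive_seed(seed, "folds"))
  per_fold <- .cv_engine(network, attributes, labeled, fold,
                         modes = c("attribute", "behavior", "both"),
                         kinds = classifier, gf = gf, seed = seed)
  list(per_fold = per_fold, summary = .summarize_folds(per_fold, by = "mode"))
}

#' Classifier comparison under shared folds and features
#'
#' @inheritParams cross_validate
#' @param kinds classifier kinds to compare.
#' @return list with `per_fold` and `summary` (one row per classifier).
#' @export
classifier_comparison <- function(network, attributes, k = 5L,
                                  kinds = c("nb", "lr", "et", "rf"),
                                  mode = "both", gf = gf_config(), seed = 1L) {
  labeled <- labeled_edge_set(network, seed)
  fold <- split_folds(labeled, k, derive_seed(seed, "folds"))
  per_fold <- .cv_engine(network, attributes, labeled, fold, modes = mode,
                         kinds = kinds, gf = gf, seed = seed)
  list(per_fold = per_fold,
       summary = .summarize_folds(per_fold, by = "classifier"))
}

#' Performance against the proportion of known edges
#'
#' For each fraction, that share of the positive edges is retained as the
#' known network: the behavior embedding is fit on it, the classifier is
#' trained on the retained edges (plus a matching share of sampled
#' negatives) using behavior-only 64-dimensional representations, and
#' evaluation uses the complementary held-out edges plus the remaining
#' negatives.
#'
#' @param network an `assoc_network`.
#' @param fractions fractions of edges retained (default 0.2, 0.4, 0.6,
#'   0.8).
#' @param classifier classifier kind.
#' @param gf a [gf_config()].
#' @param seed master seed.
#' @return data frame, one metrics row per fraction.
#' @export
proportion_sweep <- function(network, fractions = c(0.2, 0.4, 0.6, 0.8),
                             classifier = "rf", gf = gf_config(), seed = 1L) {
  rows <- list()
  for (fr in fractions) {
    tag <- paste0("frac", fr)
    sub <- subsample_edges(network, fr, derive_seed(seed, tag))
    neg <- sample_negatives(network, count = nrow(network$edges),
                            seed = derive_seed(seed, paste0(tag, "neg")))
    set.seed(derive_seed(seed, paste0(tag, "negsplit")))
    n_tr <- round(fr * nrow(neg))
    tr_neg_rows <- sample.int(nrow(neg), n_tr)
    cfg <- gf
    cfg$seed <- derive_seed(seed, paste0(tag, "gf"))
    emb <- gf_factorize(sub$train, cfg)
    reps <- node_representations(network, embedding = emb, mode = "behavior")
    tr_pos <- sub$train$edges
    te_pos <- sub$held_out
    if (length(intersect(paste(te_pos$head_index, te_pos$tail_index),
                         .pair_keys(sub$train)))) {
      stop("leakage: held-out edges present in the training network")
    }
    tr <- rbind(tr_pos[c("head_index", "tail_index")],
                neg[tr_neg_rows, c("head_index", "tail_index")])
    te <- rbind(te_pos[c("head_index", "tail_index")],
                neg[-tr_neg_rows, c("head_index", "tail_index")])
    ytr <- rep(c(1, 0), c(nrow(tr_pos), n_tr))
    yte <- rep(c(1, 0), c(nrow(te_pos), nrow(neg) - n_tr))
    model <- train_classifier(pair_features(tr, reps), ytr,
                              classifier_spec(classifier,
                                              seed = derive_seed(seed, "clf")))
    sc <- predict_scores(model, pair_features(te, reps))
    rows[[length(rows) + 1L]] <- cbind(data.frame(fraction = fr),
                                       .metric_row(yte, sc))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# embedding-like matrix (rows = all nodes) whose target-type rows hold
# SAE-compressed Gaussian interaction-profile similarities
.gip_behavior <- function(network, train_pos, type_a, type_b, dim, seed) {
  nodes <- network$nodes
  ids_a <- nodes$node_id[nodes$node_type == type_a]
  ids_b <- nodes$node_id[nodes$node_type == type_b]
  inc <- matrix(0, length(ids_a), length(ids_b),
                dimnames = list(ids_a, ids_b))
  ha <- ifelse(train_pos$head_id %in% ids_a, train_pos$head_id,
               train_pos$tail_id)
  hb <- ifelse(train_pos$head_id %in% ids_a, train_pos$tail_id,
               train_pos$head_id)
  inc[cbind(ha, hb)] <- 1
  B <- matrix(0, nrow(nodes), dim,
              dimnames = list(nodes$node_id[order(nodes$global_index)], NULL))
  for (side in list(list(ids = ids_a, K = gip_kernel(inc), tag = "a"),
                    list(ids = ids_b, K = gip_kernel(t(inc)), tag = "b"))) {
    sae <- train_sae(side$K,
                     sae_config(input_dim = ncol(side$K), hidden_dim = dim,
                                seed = derive_seed(seed, paste0("gip", side$tag))))
    B[side$ids, ] <- sae_encode(sae, side$K)
  }
  B
}

#' Local versus global behavior information on one relation type
#'
#' Compares four pipelines on a single target relation (default
#' miRNA-disease) under shared folds and negative samples: (a) attribute
#' vectors only; (b) attributes concatenated with Gaussian
#' interaction-profile similarity rows compressed to 64 dimensions; (c)
#' attributes concatenated with an embedding factorized from the target
#' sub-network only (local); (d) attributes concatenated with an
#' embedding factorized from the whole heterogeneous network (global) --
#' the full model. In every pipeline the test edges are stripped before
#' any behavior information is computed.
#'
#' @inheritParams cross_validate
#' @param target target relation type.
#' @return list with `per_fold` (fold x method metrics) and `summary`
#'   (one row per method: `attribute`, `gip`, `local_gf`, `global_gf`).
#' @export
local_vs_global <- function(network, attributes, target = "miRNA-disease",
                            k = 5L, classifier = "rf", gf = gf_config(),
                            seed = 1L) {
  rel <- relation_types()
  stopifnot(target %in% rel$relation)
  type_a <- rel$type_a[rel$relation == target]
  type_b <- rel$type_b[rel$relation == target]
  tgt_rows <- which(network$edges$relation_type == target)
  if (length(tgt_rows) == 0L) stop("no edges of relation type ", target)
  other_rows <- setdiff(seq_len(nrow(network$edges)), tgt_rows)

  tgt_net <- .edge_subset_network(network, tgt_rows)
  labeled <- labeled_edge_set(tgt_net, seed)
  labeled$pos_row <- tgt_rows[labeled$pos_row]
  fold <- split_folds(labeled, k, derive_seed(seed, "folds"))

  dim <- ncol(attributes)
  rows <- list()
  for (f in seq_len(k) - 1L) {
    tr <- labeled[fold != f, , drop = FALSE]
    te <- labeled[fold == f, , drop = FALSE]
    tr_pos_rows <- tr$pos_row[tr$label == 1]
    test_keys <- paste(te$head_index[te$label == 1],
                       te$tail_index[te$label == 1])

    behaviors <- list(attribute = NULL)
    behaviors$gip <- .gip_behavior(network,
                                   network$edges[tr_pos_rows, , drop = FALSE],
                                   type_a, type_b, dim,
                                   derive_seed(seed, paste0("gipf", f)))
    cfg_l <- gf; cfg_l$seed <- derive_seed(seed, paste0("lgf", f))
    local_net <- .edge_subset_network(network, tr_pos_rows)
    behaviors$local_gf <- gf_factorize(local_net, cfg_l)
    cfg_g <- gf; cfg_g$seed <- derive_seed(seed, paste0("ggf", f))
    global_net <- .edge_subset_network(network, c(other_rows, tr_pos_rows))
    if (length(intersect(test_keys, .pair_keys(global_net)))) {
      stop("leakage: test edges present in the global embedding graph")
    }
    behaviors$global_gf <- gf_factorize(global_net, cfg_g)

    for (method in names(behaviors)) {
      reps <- if (method == "attribute") {
        node_representations(network, attributes, mode = "attribute")
      } else {
        node_representations(network, attributes, behaviors[[method]],
                             mode = "both")
      }
      model <- train_classifier(pair_features(tr, reps), tr$label,
                                classifier_spec(classifier,
                                                seed = derive_seed(seed, "clf")))
      sc <- predict_scores(model, pair_features(te, reps))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(fold = f, method = method), .metric_row(te$label, sc))
    }
  }
  per_fold <- do.call(rbind, rows)
  rownames(per_fold) <- NULL
  list(per_fold = per_fold, summary = .summarize_folds(per_fold, by = "method"))
}

#' Leave-one-disease-out candidate ranking
#'
#' Removes every association between one disease and the candidate node
#' type (the disease keeps its edges of the other relation types, which
#' is what makes its behavior vector informative), re-fits the behavior
#' embedding and the classifier on the remaining network, then scores
#' and ranks all candidate partners of that type -- the case-study
#' protocol for recovering a disease's associations from the rest of the
#' network.
#'
#' @param network an `assoc_network`.
#' @param attributes attribute matrix.
#' @param disease_id the held-out disease.
#' @param top_n number of top candidates to return (the full ranking is
#'   also returned).
#' @param candidate_type node type to rank (default `"miRNA"`).
#' @param mode representation mode.
#' @param classifier classifier kind.
#' @param gf a [gf_config()].
#' @param seed master seed.
#' @return list with `top` (the first `top_n` rows), `ranking` (all
#'   candidates), `held_out` (the removed partner ids of
#'   `candidate_type`) and `n_removed` (total removed edges).
#' @export
leave_one_disease_out <- function(network, attributes, disease_id,
                                  top_n = 20L, candidate_type = "miRNA",
                                  mode = "both", classifier = "rf",
                                  gf = gf_config(), seed = 1L) {
  nodes <- network$nodes
  if (!disease_id %in% nodes$node_id) stop("unknown disease: ", disease_id)
  touches <- network$edges$head_id == disease_id |
    network$edges$tail_id == disease_id
  partners <- ifelse(network$edges$head_id == disease_id,
                     network$edges$tail_id, network$edges$head_id)
  inc <- touches & nodes$node_type[match(partners, nodes$node_id)] ==
    candidate_type
  if (!any(inc)) {
    stop(disease_id, " has no ", candidate_type,
         " associations to hold out")
  }
  held_out <- partners[inc]

  train_net <- .edge_subset_network(network, which(!inc))
  cfg <- gf; cfg$seed <- derive_seed(seed, "gf_case")
  emb <- gf_factorize(train_net, cfg)
  reps <- node_representations(network, attributes, emb, mode)

  # negatives pairing the disease with the candidate type are the very
  # pairs being predicted; keep them out of the training labels
  neg <- sample_negatives(train_net, count = nrow(train_net$edges),
                          seed = derive_seed(seed, "neg_case"))
  neg_partner <- ifelse(neg$head_id == disease_id, neg$tail_id,
                        ifelse(neg$tail_id == disease_id, neg$head_id, NA))
  drop <- !is.na(neg_partner) &
    nodes$node_type[match(neg_partner, nodes$node_id)] == candidate_type
  neg <- neg[!drop, , drop = FALSE]
  tr <- rbind(train_net$edges[c("head_index", "tail_index")],
              neg[c("head_index", "tail_index")])
  y <- rep(c(1, 0), c(nrow(train_net$edges), nrow(neg)))
  model <- train_classifier(pair_features(tr, reps), y,
                            classifier_spec(classifier,
                                            seed = derive_seed(seed, "clf")))
  ranking <- rank_candidates(model, network, disease_id,
                             candidate_ids = nodes$node_id[
                               nodes$node_type == candidate_type],
                             representations = reps)
  list(top = head(ranking, top_n), ranking = ranking,
       held_out = unique(held_out), n_removed = sum(inc))
}
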