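#' @useDynLib hetlink, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm rbinom predict sd uniroot plogis setNames
#' @importFrom utils read.delim write.table head tail combn
"_PACKAGE"

#' Node and relation types of the molecular association network
#'
#' The network joins five entity types through nine undirected relation
#' types. Each relation type constrains the entity types of its two
#' endpoints; relation names follow the `<typeA>-<typeB>` convention with
#' the endpoint order of the name matching the column order expected in
#' edge-list files.
#'
#' @return `node_types()` returns the five entity type names;
#'   `relation_types()` returns a data frame with columns `relation`,
#'   `type_a` and `type_b`.
#' @export
node_types <- function() {
  c("miRNA", "lncRNA", "protein", "drug", "disease")
}

#' @rdname node_types
#' @export
relation_types <- function() {
  data.frame(
    relation = c("miRNA-lncRNA", "miRNA-disease", "miRNA-protein",
                 "lncRNA-disease", "lncRNA-protein", "protein-disease",
                 "drug-protein", "drug-disease", "protein-protein"),
    type_a = c("miRNA", "miRNA", "miRNA", "lncRNA", "lncRNA", "protein",
               "drug", "drug", "protein"),
    type_b = c("lncRNA", "disease", "protein", "disease", "protein",
               "disease", "protein", "disease", "protein"),
    stringsAsFactors = FALSE
  )
}

# Deterministic, locale-independent ordering used everywhere node ids are
# enumerated. IDs are case-sensitive.
.radix_order <- function(...) order(..., method = "radix")

#' Construct a molecular association network
#'
#' Builds the validated network object from an edge table and (optionally)
#' a node table. Edges are undirected: each is stored canonically with the
#' endpoint of lower global index first, self-loops are rejected and exact
#' duplicates (same pair, same relation type) are dropped with a message.
#' The same node pair may appear under several relation types; the
#' adjacency matrix treats it as a single unweighted edge while all
#' relation labels are kept in the edge table.
#'
#' Node types are taken from `nodes` when given, otherwise inferred from
#' the relation type of each edge (the first/second id of an input row
#' plays the first/second role of the relation name). A node seen under
#' two conflicting types is an error. Global indices are a dense 0-based
#' enumeration, ordered by entity type (miRNA, lncRNA, protein, drug,
#' disease) then by id.
#'
#' @param edges data frame with columns `head_id`, `tail_id`,
#'   `relation_type` (character).
#' @param nodes optional data frame with columns `node_id`, `node_type`.
#'   May declare isolated nodes absent from `edges`.
#' @return An object of class `assoc_network`: a list with elements
#'   `nodes` (data frame `node_id`, `node_type`, `global_index`) and
#'   `edges` (data frame `head_id`, `tail_id`, `relation_type`,
#'   `head_index`, `tail_index`, canonically ordered).
#' @export
assoc_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("head_id", "tail_id", "relation_type") %in% names(edges)))
  rel <- relation_types()
  bad <- !(edges$relation_type %in% rel$relation)
  if (any(bad)) {
    stop("unknown relation_type at row(s) ", paste(head(which(bad), 5L), collapse = ", "),
         ": ", paste(unique(edges$relation_type[bad]), collapse = ", "))
  }
  edges$head_id <- as.character(edges$head_id)
  edges$tail_id <- as.character(edges$tail_id)
  if (any(edges$head_id == edges$tail_id)) {
    stop("self-loops are not allowed (row ",
         which(edges$head_id == edges$tail_id)[1L], ")")
  }

  # resolve endpoint types: declared metadata wins; otherwise the
  # first/second id of a row is assumed to play the first/second role of
  # the relation name
  m <- match(edges$relation_type, rel$relation)
  ta <- rel$type_a[m]; tb <- rel$type_b[m]
  decl <- character(0)
  if (!is.null(nodes)) {
    stopifnot(all(c("node_id", "node_type") %in% names(nodes)))
    decl <- setNames(as.character(nodes$node_type), as.character(nodes$node_id))
  }
  # propagate type constraints to a fixpoint: a typed endpoint forces its
  # partner's type through the relation; rows whose endpoints are both
  # untyped fall back to positional (name-order) interpretation only when
  # nothing else pins them down
  types <- decl[!duplicated(names(decl))]
  if (anyNA(types)) stop("node metadata contains missing types")
  repeat {
    th <- unname(types[edges$head_id]); tt <- unname(types[edges$tail_id])
    h_only <- which(!is.na(th) & is.na(tt))
    t_only <- which(is.na(th) & !is.na(tt))
    changed <- FALSE
    for (i in h_only) {
      other <- if (th[i] == ta[i]) tb[i] else if (th[i] == tb[i]) ta[i] else NA
      if (!is.na(other)) { types[edges$tail_id[i]] <- other; changed <- TRUE }
    }
    for (i in t_only) {
      other <- if (tt[i] == tb[i]) ta[i] else if (tt[i] == ta[i]) tb[i] else NA
      if (!is.na(other)) { types[edges$head_id[i]] <- other; changed <- TRUE }
    }
    if (!changed) {
      none <- which(is.na(unname(types[edges$head_id])) &
                      is.na(unname(types[edges$tail_id])))
      if (length(none) == 0L) break
      types[edges$head_id[none[1L]]] <- ta[none[1L]]
      types[edges$tail_id[none[1L]]] <- tb[none[1L]]
    }
  }
  th <- unname(types[edges$head_id]); tt <- unname(types[edges$tail_id])
  mism <- is.na(th) | is.na(tt) |
    !((th == ta & tt == tb) | (th == tb & tt == ta))
  if (any(mism)) {
    stop("endpoint type(s) do not match relation type at row(s) ",
         paste(head(which(mism), 5L), collapse = ", "))
  }
  inferred <- unique(data.frame(
    node_id = c(edges$head_id, edges$tail_id, names(types)),
    node_type = c(th, tt, unname(types)),
    stringsAsFactors = FALSE
  ))
  dupid <- inferred$node_id[duplicated(inferred$node_id)]
  if (length(dupid)) {
    stop("node(s) declared/used with conflicting types: ",
         paste(unique(dupid), collapse = ", "))
  }
  if (!all(inferred$node_type %in% node_types())) {
    stop("unknown node type(s): ",
         paste(setdiff(inferred$node_type, node_types()), collapse = ", "))
  }
  ord <- .radix_order(match(inferred$node_type, node_types()), inferred$node_id)
  nodes_df <- inferred[ord, , drop = FALSE]
  nodes_df$global_index <- seq_len(nrow(nodes_df)) - 1L
  rownames(nodes_df) <- NULL

  idx <- function(id) nodes_df$global_index[match(id, nodes_df$node_id)]
  hi <- idx(edges$head_id)
  ti <- idx(edges$tail_id)
  swap <- hi > ti
  h2 <- ifelse(swap, edges$tail_id, edges$head_id)
  t2 <- ifelse(swap, edges$head_id, edges$tail_id)
  e <- data.frame(head_id = h2, tail_id = t2,
                  relation_type = edges$relation_type,
                  head_index = pmin(hi, ti), tail_index = pmax(hi, ti),
                  stringsAsFactors = FALSE)
  key <- paste(e$head_index, e$tail_index, e$relation_type)
  ndup <- sum(duplicated(key))
  if (ndup > 0) {
    message("dropped ", ndup, " duplicate edge(s)")
    e <- e[!duplicated(key), , drop = FALSE]
  }
  e <- e[.radix_order(e$head_index, e$tail_index, e$relation_type), , drop = FALSE]
  rownames(e) <- NULL

  structure(list(nodes = nodes_df, edges = e), class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat("Molecular association network\n")
  cat("  nodes:", nrow(x$nodes), "(",
      paste(names(table(x$nodes$node_type)), table(x$nodes$node_type),
            collapse = ", "), ")\n")
  cat("  edges:", nrow(x$edges), "over",
      length(unique(x$edges$relation_type)), "relation type(s)\n")
  invisible(x)
}

#' Read / write an edge list
#'
#' The edge-list format is tab-separated UTF-8 text with three columns
#' `head_id`, `tail_id`, `relation_type` and `#`-prefixed comment lines.
#' `read_edge_list()` validates relation types (reporting the offending
#' line number), canonicalizes and deduplicates. `write_edge_list()` emits
#' the canonical edge table so that a read/write round trip reproduces the
#' edge set exactly.
#'
#' @param path file path.
#' @param node_meta optional path to a node metadata TSV with columns
#'   `node_id`, `node_type` (extra columns such as a payload reference are
#'   ignored here).
#' @return `read_edge_list()` returns an `assoc_network`.
#' @export
read_edge_list <- function(path, node_meta = NULL) {
  raw <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  lineno <- which(keep)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    stop("parse error at line ", lineno[which(nf < 3L)[1L]],
         ": expected >= 3 tab-separated fields")
  }
  edges <- data.frame(
    head_id = vapply(parts, `[[`, "", 1L),
    tail_id = vapply(parts, `[[`, "", 2L),
    relation_type = vapply(parts, `[[`, "", 3L),
    stringsAsFactors = FALSE
  )
  bad <- !(edges$relation_type %in% relation_types()$relation)
  if (any(bad)) {
    stop("unknown relation_type '", edges$relation_type[which(bad)[1L]],
         "' at line ", lineno[which(bad)[1L]])
  }
  nodes <- NULL
  if (!is.null(node_meta)) {
    nm <- read.delim(node_meta, header = FALSE, comment.char = "#",
                     stringsAsFactors = FALSE)
    nodes <- data.frame(node_id = nm[[1L]], node_type = nm[[2L]],
                        stringsAsFactors = FALSE)
  }
  net <- assoc_network(edges, nodes)
  # duplicate-pair bookkeeping: pairs repeated across relation types count
  # once in the adjacency matrix but keep every relation label
  npair <- length(unique(paste(net$edges$head_index, net$edges$tail_index)))
  if (npair < nrow(net$edges)) {
    message(nrow(net$edges), " typed edges over ", npair,
            " distinct node pairs (cross-type duplicates retained)")
  }
  net
}

#' @rdname read_edge_list
#' @param network an `assoc_network`.
#' @export
write_edge_list <- function(network, path) {
  e <- network$edges
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# head_id\ttail_id\trelation_type", con)
  writeLines(paste(e$head_id, e$tail_id, e$relation_type, sep = "\t"), con)
  invisible(path)
}

#' Symmetric adjacency matrix of a network
#'
#' Returns the unweighted adjacency matrix `Y` (0/1, symmetric, zero
#' diagonal) over all nodes in global-index order. A node pair linked by
#' several relation types contributes a single 1.
#'
#' @param network an `assoc_network`.
#' @param sparse return a `Matrix::sparseMatrix` (default) or a dense base
#'   matrix.
#' @return n x n symmetric 0/1 matrix with dimnames set to node ids.
#' @export
adjacency_matrix <- function(network, sparse = TRUE) {
  n <- nrow(network$nodes)
  pair <- unique(network$edges[, c("head_index", "tail_index")])
  Y <- Matrix::sparseMatrix(
    i = c(pair$head_index, pair$tail_index) + 1L,
    j = c(pair$tail_index, pair$head_index) + 1L,
    x = 1, dims = c(n, n),
    dimnames = list(network$nodes$node_id, network$nodes$node_id)
  )
  if (!sparse) Y <- as.matrix(Y)
  Y
}

# distinct unordered node pairs of a network, as a character key
.pair_keys <- function(network) {
  unique(paste(network$edges$head_index, network$edges$tail_index))
}

# legal (ordered-by-index) candidate pair space size for one relation type
.pair_space <- function(nodes_df, type_a, type_b) {
  ia <- nodes_df$global_index[nodes_df$node_type == type_a]
  ib <- nodes_df$global_index[nodes_df$node_type == type_b]
  if (type_a == type_b) {
    list(a = ia, b = ib, size = length(ia) * (length(ia) - 1) / 2)
  } else {
    list(a = ia, b = ib, size = length(ia) * length(ib))
  }
}

#' Sample negative (unconfirmed) relationships
#'
#' Draws node pairs that are not present in the positive edge set, to act
#' as negative examples for the link classifier. Sampling is stratified by
#' relation type: the number of negatives drawn for each type is
#' proportional to that type's share of positive edges (equal to it when
#' `count` equals the number of positives), so the classifier cannot learn
#' relation-type priors. Endpoints are drawn uniformly from the nodes of
#' the legal endpoint types; pairs positive under *any* relation type are
#' excluded, as are self pairs and duplicates.
#'
#' @param network an `assoc_network`.
#' @param count total number of negatives (default: number of positive
#'   edges, giving a balanced set).
#' @param seed integer seed; the same seed reproduces the same sample.
#' @return data frame like `network$edges` with an added `label` column
#'   equal to 0.
#' @export
sample_negatives <- function(network, count = nrow(network$edges), seed) {
  stopifnot(count >= 0)
  set.seed(seed)
  rel <- relation_types()
  pos_by_type <- table(factor(network$edges$relation_type, levels = rel$relation))
  # largest-remainder apportionment of `count` across types
  share <- as.numeric(pos_by_type) / sum(pos_by_type) * count
  n_type <- floor(share)
  rem <- count - sum(n_type)
  if (rem > 0) {
    o <- order(share - n_type, decreasing = TRUE)
    n_type[o[seq_len(rem)]] <- n_type[o[seq_len(rem)]] + 1L
  }
  names(n_type) <- rel$relation
  pos_keys <- .pair_keys(network)

  out <- vector("list", nrow(rel))
  for (r in seq_len(nrow(rel))) {
    need <- n_type[[r]]
    if (need == 0) next
    sp <- .pair_space(network$nodes, rel$type_a[r], rel$type_b[r])
    n_pos_pairs_type <- sum(network$edges$relation_type == rel$relation[r])
    if (sp$size - n_pos_pairs_type < need) {
      stop("insufficient negatives for relation type '", rel$relation[r],
           "': pair space ", sp$size, ", positives ", n_pos_pairs_type,
           ", requested ", need)
    }
    got <- character(0)
    gi <- integer(0); gj <- integer(0)
    tries <- 0L
    while (length(got) < need) {
      tries <- tries + 1L
      m <- max(2L * (need - length(got)), 32L)
      i <- sample(sp$a, m, replace = TRUE)
      j <- sample(sp$b, m, replace = TRUE)
      lo <- pmin(i, j); hi <- pmax(i, j)
      ok <- lo != hi
      key <- paste(lo, hi)
      ok <- ok & !(key %in% pos_keys) & !(key %in% got) & !duplicated(key)
      if (any(ok)) {
        take <- which(ok)[seq_len(min(sum(ok), need - length(got)))]
        got <- c(got, key[take])
        gi <- c(gi, lo[take]); gj <- c(gj, hi[take])
      }
      if (tries > 10000L) {
        # saturated space reached through rejection; enumerate instead
        all_i <- rep(sp$a, each = length(sp$b))
        all_j <- rep(sp$b, times = length(sp$a))
        lo <- pmin(all_i, all_j); hi <- pmax(all_i, all_j)
        key <- paste(lo, hi)
        keep <- lo != hi & !duplicated(key) & !(key %in% pos_keys) & !(key %in% got)
        pick <- sample(which(keep), need - length(got))
        gi <- c(gi, lo[pick]); gj <- c(gj, hi[pick])
        break
      }
    }
    ids <- network$nodes$node_id[order(network$nodes$global_index)]
    out[[r]] <- data.frame(head_id = ids[gi + 1L], tail_id = ids[gj + 1L],
                           relation_type = rel$relation[r],
                           head_index = gi, tail_index = gj,
                           stringsAsFactors = FALSE)
  }
  neg <- do.call(rbind, out)
  neg <- neg[.radix_order(neg$head_index, neg$tail_index, neg$relation_type), ,
             drop = FALSE]
  rownames(neg) <- NULL
  neg$label <- 0
  neg
}

#' Split labeled edges into cross-validation folds
#'
#' Shuffles and deals edges round-robin into `k` mutually exclusive folds
#' of near-equal size (max - min <= 1), stratified by label when a `label`
#' column is present so positives and negatives are each split evenly.
#'
#' @param edges data frame of labeled edges (optionally with a `label`
#'   column of 0/1).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return integer vector of fold assignments in `0:(k-1)`, one per row of
#'   `edges`.
#' @export
split_folds <- function(edges, k = 5L, seed) {
  n <- nrow(edges)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k (", k, ") exceeds number of edges (", n, ")")
  set.seed(seed)
  fold <- integer(n)
  if (!is.null(edges$label)) {
    groups <- split(seq_len(n), edges$label)
  } else {
    groups <- list(seq_len(n))
  }
  offset <- 0L
  for (g in groups) {
    perm <- sample(g)
    fold[perm] <- (offset + seq_along(perm) - 1L) %% k
    offset <- (offset + length(perm)) %% k
  }
  fold
}

#' Retain a fraction of edges as the known network
#'
#' Splits the positive edge set into a retained ("known") part and a
#' held-out complement, as used when studying performance against the
#' proportion of training edges. The node set is unchanged; nodes may
#' become isolated in the training network.
#'
#' @param network an `assoc_network`.
#' @param fraction fraction of edges to retain, in (0, 1); the retained
#'   count is `round(fraction * |edges|)`.
#' @param seed integer seed.
#' @return list with elements `train` (an `assoc_network` on the full node
#'   set) and `held_out` (data frame of the complementary edges).
#' @export
subsample_edges <- function(network, fraction, seed) {
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  set.seed(seed)
  n <- nrow(network$edges)
  n_keep <- round(fraction * n)
  keep <- sort(sample.int(n, n_keep))
  train <- assoc_network(network$edges[keep, c("head_id", "tail_id", "relation_type")],
                         nodes = network$nodes[, c("node_id", "node_type")])
  held <- network$edges[-keep, , drop = FALSE]
  rownames(held) <- NULL
  list(train = train, held_out = held)
}

# Restrict a network to a subset of positive edges (by row index), keeping
# the full node set and the global indices intact.
.edge_subset_network <- function(network, rows) {
  assoc_network(network$edges[rows, c("head_id", "tail_id", "relation_type")],
                nodes = network$nodes[, c("node_id", "node_type")])
}
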