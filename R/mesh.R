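#' Build the MeSH DAG of a disease
#'
#' A disease is located in the MeSH hierarchy by one or more dot-separated
#' tree numbers (e.g. `"C04.588.274"`); every prefix obtained by dropping
#' trailing `.xxx` segments is an ancestor. The DAG of a disease `D`
#' consists of `D` itself (identified with the set of its full tree
#' numbers) plus the union of the ancestors of all its tree numbers, with
#' child-to-parent edges.
#'
#' @param disease_id identifier of the disease.
#' @param tree_numbers character vector of MeSH tree numbers.
#' @return A `disease_dag`: list with `disease_id`, `terms` (all tree
#'   numbers in `N(D)`), `self` (the disease's own tree numbers),
#'   `parent_of` (named list: term -> parent terms within the DAG) and
#'   `depth` (named integer: generations removed from the nearest own
#'   term; 0 for `self`).
#' @export
build_disease_dag <- function(disease_id, tree_numbers) {
  tree_numbers <- unique(as.character(tree_numbers))
  if (length(tree_numbers) == 0L) stop("no tree numbers for ", disease_id)
  ok <- grepl("^[A-Z][0-9A-Za-z]*(\\.[0-9A-Za-z]+)*$", tree_numbers)
  if (!all(ok)) {
    stop("malformed tree number for ", disease_id, ": ",
         paste(tree_numbers[!ok], collapse = ", "))
  }
  ancestors <- function(tn) {
    parts <- strsplit(tn, ".", fixed = TRUE)[[1L]]
    vapply(seq_along(parts),
           function(i) paste(parts[seq_len(i)], collapse = "."), "")
  }
  chains <- lapply(tree_numbers, ancestors)
  terms <- unique(unlist(chains))
  # child -> parent edges: within each chain, term i's parent is term i-1
  parent_of <- setNames(vector("list", length(terms)), terms)
  for (ch in chains) {
    if (length(ch) > 1L) {
      for (i in 2:length(ch)) {
        parent_of[[ch[i]]] <- union(parent_of[[ch[i]]], ch[i - 1L])
      }
    }
  }
  # depth = fewest child->parent steps from any of the disease's own tree
  # numbers; the max rule of the contribution then reduces to delta^depth
  depth <- setNames(rep(NA_integer_, length(terms)), terms)
  for (ch in chains) {
    L <- length(ch)
    for (i in seq_len(L)) {
      d <- L - i
      if (is.na(depth[ch[i]]) || depth[ch[i]] > d) depth[ch[i]] <- d
    }
  }
  structure(list(disease_id = disease_id, terms = terms,
                 self = tree_numbers, parent_of = parent_of, depth = depth),
            class = "disease_dag")
}

#' Semantic contribution of each DAG term to its disease
#'
#' The disease contributes 1 to itself; any other term `t` in the DAG
#' contributes `max(delta * contribution(t'))` over its children `t'`, so
#' contributions decay geometrically with the attenuation factor `delta`
#' along ancestor chains and the most direct path dominates when a term is
#' reachable at several depths.
#'
#' @param dag a [build_disease_dag()] result.
#' @param delta attenuation factor in (0, 1); default 0.5.
#' @return named numeric vector over `dag$terms`; the disease's own terms
#'   get exactly 1.
#' @export
contribution_map <- function(dag, delta = 0.5) {
  if (!(delta > 0 && delta < 1)) stop("delta must be in (0, 1)")
  # depth is the minimum number of child->parent steps from an own term,
  # so the max rule reduces to delta^depth
  contrib <- delta^dag$depth
  names(contrib) <- dag$terms
  contrib
}

#' Semantic value of a disease
#'
#' Sum of the contributions of every term in the disease's DAG; at least 1
#' since the disease contributes 1 to itself.
#'
#' @inheritParams contribution_map
#' @return scalar `DV1(D)`.
#' @export
semantic_value <- function(dag, delta = 0.5) {
  sum(contribution_map(dag, delta))
}

#' Semantic similarity between two diseases
#'
#' Generalized-Jaccard similarity of two disease DAGs: the contributions
#' (from each side) of the terms shared by both DAGs, divided by the sum
#' of the two semantic values. Symmetric, bounded in [0, 1]; 1 for
#' identical DAGs, 0 for disjoint ones.
#'
#' @param dag_i,dag_j [build_disease_dag()] results (built with the same
#'   hierarchy conventions).
#' @param delta attenuation factor used for both sides.
#' @return similarity in [0, 1].
#' @export
disease_similarity <- function(dag_i, dag_j, delta = 0.5) {
  ci <- contribution_map(dag_i, delta)
  cj <- contribution_map(dag_j, delta)
  shared <- intersect(dag_i$terms, dag_j$terms)
  if (length(shared) == 0L) return(0)
  sum(ci[shared] + cj[shared]) / (sum(ci) + sum(cj))
}

#' Pairwise disease similarity matrix
#'
#' @param dags named list of [build_disease_dag()] objects.
#' @param delta attenuation factor.
#' @return symmetric matrix with unit diagonal; dimnames are the disease
#'   ids. This raw similarity profile (one row per disease) is the disease
#'   attribute later compressed to 64 dimensions by the sparse
#'   autoencoder.
#' @export
disease_similarity_profile <- function(dags, delta = 0.5) {
  n <- length(dags)
  stopifnot(n >= 1L)
  ids <- vapply(dags, `[[`, "", "disease_id")
  contribs <- lapply(dags, contribution_map, delta = delta)
  dv <- vapply(contribs, sum, 0)
  S <- diag(1, n)
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        shared <- intersect(dags[[i]]$terms, dags[[j]]$terms)
        s <- if (length(shared)) {
          sum(contribs[[i]][shared] + contribs[[j]][shared]) / (dv[i] + dv[j])
        } else 0
        S[i, j] <- S[j, i] <- s
      }
    }
  }
  dimnames(S) <- list(ids, ids)
  S
}

#' Read a disease descriptor table
#'
#' TSV with columns `node_id`, `tree_number` (one row per tree number,
#' `#` comments ignored); returns one DAG per disease.
#'
#' @param path file path.
#' @return named list of `disease_dag` objects.
#' @export
read_mesh_table <- function(path) {
  tab <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  names(tab)[1:2] <- c("node_id", "tree_number")
  by_id <- split(tab$tree_number, tab$node_id)
  out <- lapply(names(by_id), function(id) build_disease_dag(id, by_id[[id]]))
  names(out) <- names(by_id)
  out[.radix_order(names(out))]
}
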