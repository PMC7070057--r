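# Derive a reproducible sub-stream seed from a master seed and a stage
# label; kept well inside the 32-bit integer range.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}

#' Specification of a synthetic molecular association network
#'
#' The generator plants a low-rank structure: every node carries a latent
#' vector `u ~ N(0, I_d)` and each legal pair (i, j) of a relation type
#' becomes an edge with probability
#' `(1 - noise_rate) * plogis(latent_scale * <u_i, u_j> + b_rel) +
#'  noise_rate * density`,
#' with the intercept `b_rel` calibrated per relation so the expected
#' density matches the target. Attribute payloads (sequences, disease
#' tree numbers, fingerprints) are tilted by the same latent vectors with
#' strength `signal`, so attribute and behavior information can be
#' switched on and off independently.
#'
#' @param n_mirna,n_lncrna,n_protein,n_drug,n_disease node counts
#'   (defaults 120/100/150/80/90).
#' @param latent_dim latent dimension `d` (default 8, well below the
#'   embedding rank so factorization capacity is never the bottleneck).
#' @param density target edge density per relation type; either a single
#'   number (default 0.05) or a named vector over relation types.
#' @param latent_scale slope `a_rel` of the logistic link (default 3:
#'   edges strongly determined by the planted structure, emulating the
#'   high-signal regime of curated association networks).
#' @param signal attribute signal strength `s` in [0, 1] (default 0.8).
#' @param seq_len_range nucleotide/residue sequence length bounds
#'   (default 200-1000).
#' @param noise_rate fraction of purely random edge mass (default 0.02,
#'   mimicking a small unconfirmed-relationship contamination).
#' @param n_bits fingerprint length (default 256).
#' @param dag_depth,dag_branching disease hierarchy shape (default 3 / 3).
#' @param seed master seed; all per-stage streams derive from it.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_mirna = 120L, n_lncrna = 100L, n_protein = 150L,
                           n_drug = 80L, n_disease = 90L, latent_dim = 8L,
                           density = 0.05, latent_scale = 3, signal = 0.8,
                           noise_rate = 0.02, seq_len_range = c(200L, 1000L),
                           n_bits = 256L, dag_depth = 3L, dag_branching = 3L,
                           seed = 1L) {
  stopifnot(latent_dim >= 1L, all(density > 0), all(density < 1),
            signal >= 0, signal <= 1, noise_rate >= 0, noise_rate < 1,
            n_bits >= latent_dim, dag_depth >= 1L)
  rels <- relation_types()$relation
  if (length(density) == 1L) density <- setNames(rep(density, 9L), rels)
  stopifnot(all(rels %in% names(density)))
  structure(list(
    n = c(miRNA = as.integer(n_mirna), lncRNA = as.integer(n_lncrna),
          protein = as.integer(n_protein), drug = as.integer(n_drug),
          disease = as.integer(n_disease)),
    latent_dim = as.integer(latent_dim), density = density[rels],
    latent_scale = latent_scale, signal = signal, noise_rate = noise_rate,
    seq_len_range = as.integer(seq_len_range), n_bits = as.integer(n_bits),
    dag_depth = as.integer(dag_depth), dag_branching = as.integer(dag_branching),
    seed = as.integer(seed)), class = "synthetic_spec")
}

# node id tables for a spec: mi0001 ..., ln0001 ..., etc.
.synthetic_nodes <- function(spec) {
  prefix <- c(miRNA = "mi", lncRNA = "ln", protein = "pr",
              drug = "dr", disease = "di")
  do.call(rbind, lapply(node_types(), function(ty) {
    data.frame(node_id = sprintf("%s%04d", prefix[[ty]], seq_len(spec$n[[ty]])),
               node_type = ty, stringsAsFactors = FALSE)
  }))
}

#' Generate a synthetic network with planted low-rank structure
#'
#' @param spec a [synthetic_spec()].
#' @return list with `network` (an `assoc_network` over the full node
#'   set, isolated nodes included) and `latents` (matrix of latent
#'   vectors, rownames = node ids).
#' @export
generate_network <- function(spec) {
  nodes <- .synthetic_nodes(spec)
  set.seed(derive_seed(spec$seed, "latents"))
  U <- matrix(rnorm(nrow(nodes) * spec$latent_dim), nrow(nodes), spec$latent_dim)
  rownames(U) <- nodes$node_id

  rel <- relation_types()
  set.seed(derive_seed(spec$seed, "edges"))
  out <- vector("list", nrow(rel))
  for (r in seq_len(nrow(rel))) {
    ia <- nodes$node_id[nodes$node_type == rel$type_a[r]]
    ib <- nodes$node_id[nodes$node_type == rel$type_b[r]]
    if (rel$type_a[r] == rel$type_b[r]) {
      pr <- t(utils::combn(ia, 2L))
    } else {
      pr <- cbind(rep(ia, each = length(ib)), rep(ib, times = length(ia)))
    }
    g <- rowSums(U[pr[, 1L], , drop = FALSE] * U[pr[, 2L], , drop = FALSE])
    a <- spec$latent_scale
    target <- spec$density[[rel$relation[r]]]
    b <- uniroot(function(b) mean(plogis(a * g + b)) - target,
                 interval = c(-50, 50), tol = 1e-9)$root
    p <- (1 - spec$noise_rate) * plogis(a * g + b) + spec$noise_rate * target
    hit <- runif(length(p)) < p
    achieved <- mean(hit)
    if (abs(achieved - target) > 0.5 * target + 3 * sqrt(target / length(p))) {
      warning("relation ", rel$relation[r], ": achieved density ",
              signif(achieved, 3), " vs target ", target)
    }
    out[[r]] <- data.frame(head_id = pr[hit, 1L], tail_id = pr[hit, 2L],
                           relation_type = rel$relation[r],
                           stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, out)
  list(network = assoc_network(edges, nodes = nodes), latents = U)
}

# sample one sequence from a k-mer emission distribution as a
# concatenation of sampled 3-mer tokens
.sample_sequence <- function(kmers, prob, len_range) {
  n_tok <- sample(seq(floor(len_range[1L] / 3), floor(len_range[2L] / 3)), 1L)
  paste(sample(kmers, n_tok, replace = TRUE, prob = prob), collapse = "")
}

#' Generate latent-tilted sequences for ncRNA and protein nodes
#'
#' Each node's sequence is a concatenation of 3-mer tokens drawn from a
#' mixture `(1 - s) * uniform + s * softmax(M u)` where `M` is a fixed
#' seeded random map from the latent space to 3-mer logits. At `s = 0`
#' the composition carries no information about the latent structure; at
#' `s = 1` it is maximally tilted. Protein group 3-mers are re-expanded
#' to concrete residues drawn uniformly within each polarity group.
#'
#' @param nodes data frame with `node_id`, `node_type` (miRNA, lncRNA
#'   and/or protein rows).
#' @param latents latent matrix with node-id rownames.
#' @param signal tilt strength `s` in [0, 1].
#' @param seq_len_range length bounds.
#' @param seed integer seed.
#' @return named character vector of sequences.
#' @export
generate_sequences <- function(nodes, latents, signal, seq_len_range = c(90L, 300L),
                               seed) {
  set.seed(seed)
  rna_spec <- kmer_spec()
  grp_spec <- kmer_spec(alphabet = c("1", "2", "3", "4"))
  M <- matrix(rnorm(64 * ncol(latents)), 64, ncol(latents))
  groups <- split(names(polarity_groups()), polarity_groups())
  out <- character(nrow(nodes))
  names(out) <- nodes$node_id
  for (i in seq_len(nrow(nodes))) {
    u <- latents[nodes$node_id[i], ]
    logits <- as.numeric(M %*% u)
    tilt <- exp(logits - max(logits))
    prob <- (1 - signal) / 64 + signal * tilt / sum(tilt)
    if (nodes$node_type[i] == "protein") {
      toks <- strsplit(.sample_sequence(grp_spec$kmers, prob, seq_len_range),
                       "", fixed = TRUE)[[1L]]
      out[i] <- paste(vapply(toks, function(gch) sample(groups[[gch]], 1L), ""),
                      collapse = "")
    } else {
      out[i] <- .sample_sequence(rna_spec$kmers, prob, seq_len_range)
    }
  }
  out
}

#' Generate a MeSH-style disease hierarchy
#'
#' Builds complete trees of the requested depth and branching factor and
#' places each disease on its own leaf, so sibling diseases share
#' ancestors and their semantic similarity is non-trivial. When `order`
#' is given (e.g. a latent coordinate), diseases are laid out along the
#' leaf sequence in that order, making tree proximity weakly informative
#' about latent proximity; otherwise placement is a seeded shuffle. At
#' `depth = 1` every disease sits on a distinct root and all pairwise
#' similarities between distinct diseases are 0.
#'
#' @param disease_ids character vector.
#' @param depth levels per tree (root = level 1).
#' @param branching children per internal node.
#' @param seed integer seed.
#' @param order optional numeric vector (same length) controlling leaf
#'   placement.
#' @return data frame `node_id`, `tree_number` (one tree number per
#'   disease).
#' @export
generate_disease_dag_forest <- function(disease_ids, depth = 3L,
                                        branching = 3L, seed, order = NULL) {
  n <- length(disease_ids)
  stopifnot(depth >= 1L, branching >= 1L)
  leaves_per_root <- branching^(depth - 1L)
  n_roots <- ceiling(n / leaves_per_root)
  leaf_codes <- unlist(lapply(seq_len(n_roots), function(r) {
    codes <- sprintf("C%02d", r)
    for (lvl in seq_len(depth - 1L)) {
      codes <- as.vector(vapply(codes, function(cd) {
        paste0(cd, ".", sprintf("%03d", seq_len(branching)))
      }, character(branching)))
    }
    codes
  }))
  set.seed(seed)
  pos <- if (is.null(order)) sample.int(n) else rank(order, ties.method = "first")
  data.frame(node_id = disease_ids,
             tree_number = leaf_codes[pos],
             stringsAsFactors = FALSE)
}

#' Generate latent-tilted drug fingerprints
#'
#' Bit `b` of drug `i` is 1 with probability `plogis(s * <w_b, u_i>)`
#' for fixed seeded random directions `w_b`; at `s = 0` every bit is an
#' independent fair coin.
#'
#' @param drug_ids character vector.
#' @param latents latent matrix with node-id rownames.
#' @param n_bits fingerprint length.
#' @param signal tilt strength `s`.
#' @param seed integer seed.
#' @return 0/1 matrix, one row per drug.
#' @export
generate_fingerprints <- function(drug_ids, latents, n_bits = 256L, signal,
                                  seed) {
  set.seed(seed)
  W <- matrix(rnorm(n_bits * ncol(latents)), n_bits, ncol(latents))
  U <- latents[drug_ids, , drop = FALSE]
  P <- plogis(signal * tcrossprod(U, W))
  B <- matrix(as.integer(runif(length(P)) < P), nrow(P), ncol(P))
  rownames(B) <- drug_ids
  B
}

#' Generate a complete synthetic dataset
#'
#' Runs the network, sequence, hierarchy and fingerprint generators under
#' one master seed and returns everything the pipeline consumes.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `network`, `latents`, `sequences` (named character
#'   vector over miRNA/lncRNA/protein nodes), `dags` (named list of
#'   `disease_dag`), `mesh_table` (the tree-number table behind `dags`),
#'   `fingerprints` (0/1 matrix over drug nodes) and the `spec`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  net <- generate_network(spec)
  nodes <- net$network$nodes
  seq_nodes <- nodes[nodes$node_type %in% c("miRNA", "lncRNA", "protein"), ]
  sequences <- generate_sequences(seq_nodes, net$latents, spec$signal,
                                  spec$seq_len_range,
                                  derive_seed(spec$seed, "sequences"))
  disease_ids <- nodes$node_id[nodes$node_type == "disease"]
  ord <- if (spec$signal > 0) net$latents[disease_ids, 1L] else NULL
  mesh_table <- generate_disease_dag_forest(
    disease_ids, spec$dag_depth, spec$dag_branching,
    derive_seed(spec$seed, "mesh"), order = ord)
  dags <- lapply(seq_len(nrow(mesh_table)), function(i) {
    build_disease_dag(mesh_table$node_id[i], mesh_table$tree_number[i])
  })
  names(dags) <- mesh_table$node_id
  fingerprints <- generate_fingerprints(
    nodes$node_id[nodes$node_type == "drug"], net$latents, spec$n_bits,
    spec$signal, derive_seed(spec$seed, "fingerprints"))
  list(network = net$network, latents = net$latents, sequences = sequences,
       dags = dags, mesh_table = mesh_table, fingerprints = fingerprints,
       spec = spec)
}

#' Write a synthetic dataset to the standard on-disk formats
#'
#' Emits `edges.tsv`, `nodes.tsv`, `rna.fasta`, `protein.fasta`,
#' `mesh.tsv`, `fingerprints.tsv` and `latents.tsv` under `dir`,
#' exactly the formats the loaders consume.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- dataset$network
  write_edge_list(net, file.path(dir, "edges.tsv"))
  write.table(net$nodes[, c("node_id", "node_type")],
              file.path(dir, "nodes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  seq_types <- net$nodes$node_type[match(names(dataset$sequences),
                                         net$nodes$node_id)]
  is_prot <- seq_types == "protein"
  writeLines(paste0(">", names(dataset$sequences)[!is_prot], "\n",
                    dataset$sequences[!is_prot]),
             file.path(dir, "rna.fasta"))
  writeLines(paste0(">", names(dataset$sequences)[is_prot], "\n",
                    dataset$sequences[is_prot]),
             file.path(dir, "protein.fasta"))
  write.table(dataset$mesh_table, file.path(dir, "mesh.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  fp <- apply(dataset$fingerprints, 1L, paste, collapse = "")
  writeLines(paste(rownames(dataset$fingerprints), fp, sep = "\t"),
             file.path(dir, "fingerprints.tsv"))
  lat <- data.frame(node_id = rownames(dataset$latents), dataset$latents)
  write.table(lat, file.path(dir, "latents.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
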