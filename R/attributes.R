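#' Compute 64-dimensional attribute vectors for every node
#'
#' Applies the type-appropriate attribute encoder to each node:
#' normalized 3-mer composition for miRNA/lncRNA, reduced-alphabet 3-mer
#' composition for proteins, and sparse-autoencoder codes of the raw
#' attribute for diseases (their semantic-similarity profile row) and
#' drugs (their fingerprint). One autoencoder is trained per node type
#' needing compression, since the raw dimensions differ. Attribute
#' vectors depend only on node payloads, never on the edge set, so they
#' can be computed once and reused across cross-validation folds without
#' information leakage.
#'
#' @param network an `assoc_network`.
#' @param sequences named character vector of sequences for every
#'   miRNA/lncRNA/protein node.
#' @param dags named list of `disease_dag` objects for every disease
#'   node.
#' @param fingerprints 0/1 matrix (rownames = drug ids) for every drug
#'   node.
#' @param delta MeSH attenuation factor (default 0.5).
#' @param dim attribute dimension (default 64).
#' @param sae_epochs,seed sparse-autoencoder training schedule and seed.
#' @return list with `attributes` (matrix, one 64-dim row per node,
#'   rownames = node ids), `similarity` (the raw disease similarity
#'   matrix) and the trained `sae_disease` / `sae_drug` models (NULL for
#'   absent types).
#' @export
compute_attributes <- function(network, sequences = NULL, dags = NULL,
                               fingerprints = NULL, delta = 0.5, dim = 64L,
                               sae_epochs = 100L, seed = 1L) {
  nodes <- network$nodes
  A <- matrix(0, nrow(nodes), dim,
              dimnames = list(nodes$node_id[order(nodes$global_index)], NULL))

  need <- function(ids, have, what) {
    miss <- setdiff(ids, have)
    if (length(miss)) {
      stop("missing ", what, " for: ", paste(head(miss, 5L), collapse = ", "))
    }
  }
  rna_ids <- nodes$node_id[nodes$node_type %in% c("miRNA", "lncRNA")]
  prot_ids <- nodes$node_id[nodes$node_type == "protein"]
  dis_ids <- nodes$node_id[nodes$node_type == "disease"]
  drug_ids <- nodes$node_id[nodes$node_type == "drug"]

  if (length(c(rna_ids, prot_ids))) {
    need(c(rna_ids, prot_ids), names(sequences), "sequence")
    for (id in rna_ids) A[id, ] <- encode_rna_kmer(sequences[[id]])
    for (id in prot_ids) A[id, ] <- encode_protein_kmer(sequences[[id]])
  }

  sim <- NULL; sae_dis <- NULL
  if (length(dis_ids)) {
    need(dis_ids, names(dags), "disease DAG")
    sim <- disease_similarity_profile(dags[dis_ids], delta = delta)
    sae_dis <- train_sae(sim, sae_config(input_dim = ncol(sim),
                                         hidden_dim = dim,
                                         epochs = sae_epochs,
                                         seed = derive_seed(seed, "sae_dis")))
    A[dis_ids, ] <- sae_encode(sae_dis, sim[dis_ids, , drop = FALSE])
  }

  sae_drug <- NULL
  if (length(drug_ids)) {
    need(drug_ids, rownames(fingerprints), "fingerprint")
    fp <- fingerprints[drug_ids, , drop = FALSE]
    sae_drug <- train_sae(fp, sae_config(input_dim = ncol(fp),
                                         hidden_dim = dim,
                                         epochs = sae_epochs,
                                         seed = derive_seed(seed, "sae_drug")))
    A[drug_ids, ] <- sae_encode(sae_drug, fp)
  }

  list(attributes = A, similarity = sim,
       sae_disease = sae_dis, sae_drug = sae_drug)
}
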