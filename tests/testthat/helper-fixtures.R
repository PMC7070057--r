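# Shared fixtures, built in code. The small synthetic dataset is cached
# per session so several test files can reuse it.

tiny_edges <- function() {
  data.frame(
    head_id = c("mirA", "mirA", "lncB", "drugX"),
    tail_id = c("disA", "protC", "disA", "protC"),
    relation_type = c("miRNA-disease", "miRNA-protein", "lncRNA-disease",
                      "drug-protein"),
    stringsAsFactors = FALSE
  )
}

.fixture_env <- new.env(parent = emptyenv())

small_spec <- function(seed = 42L) {
  synthetic_spec(n_mirna = 30L, n_lncrna = 25L, n_protein = 35L,
                 n_drug = 20L, n_disease = 22L, seq_len_range = c(120L, 400L),
                 n_bits = 64L, seed = seed)
}

small_dataset <- function() {
  if (is.null(.fixture_env$ds)) .fixture_env$ds <- generate_dataset(small_spec())
  .fixture_env$ds
}

small_attributes <- function() {
  if (is.null(.fixture_env$at)) {
    ds <- small_dataset()
    .fixture_env$at <- compute_attributes(ds$network, ds$sequences, ds$dags,
                                          ds$fingerprints, sae_epochs = 40L,
                                          seed = 42L)$attributes
  }
  .fixture_env$at
}

fast_gf <- function(seed = 1L) gf_config(rank = 16L, max_epochs = 150L, seed = seed)

# independent brute-force AUC: pairwise-comparison estimator, ties 1/2
brute_auc <- function(labels, scores) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
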