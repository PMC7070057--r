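test_that("edge counts track the calibrated density targets", {
  ds <- small_dataset()
  rel <- relation_types()
  n_by_type <- table(ds$network$nodes$node_type)
  counts <- table(factor(ds$network$edges$relation_type,
                         levels = rel$relation))
  for (r in seq_len(nrow(rel))) {
    na <- n_by_type[[rel$type_a[r]]]; nb <- n_by_type[[rel$type_b[r]]]
    n_pairs <- if (rel$type_a[r] == rel$type_b[r]) na * (na - 1) / 2 else na * nb
    expected <- 0.05 * n_pairs
    sigma <- sqrt(n_pairs * 0.05 * 0.95)
    expect_lt(abs(counts[[rel$relation[r]]] - expected), 4 * sigma)
  }
})

test_that("generation is deterministic in the master seed", {
  s <- small_spec()
  g1 <- generate_network(s)
  g2 <- generate_network(s)
  expect_identical(g1$network$edges, g2$network$edges)
  expect_identical(g1$latents, g2$latents)
  d1 <- generate_dataset(s)
  expect_identical(d1$sequences, generate_dataset(s)$sequences)
  expect_identical(d1$fingerprints, generate_dataset(s)$fingerprints)
})

test_that("zero latent scale yields edges unrelated to the latent structure", {
  s <- small_spec()
  s$latent_scale <- 0
  g <- generate_network(s)
  U <- g$latents
  e <- g$network$edges
  ip_edges <- rowSums(U[e$head_id, ] * U[e$tail_id, ])
  # inner products on edges look like inner products on random pairs
  set.seed(1)
  ids <- rownames(U)
  ip_rand <- rowSums(U[sample(ids, 500, TRUE), ] * U[sample(ids, 500, TRUE), ])
  expect_lt(abs(mean(ip_edges) - mean(ip_rand)), 0.5)
})

test_that("sequence composition carries latent signal only when s > 0", {
  set.seed(2)
  nodes <- data.frame(node_id = sprintf("m%03d", 1:200), node_type = "miRNA")
  U <- matrix(rnorm(200 * 4), 200, 4, dimnames = list(nodes$node_id, NULL))

  seq0 <- generate_sequences(nodes, U, signal = 0,
                             seq_len_range = c(300L, 600L), seed = 5)
  K0 <- t(vapply(seq0, encode_rna_kmer, numeric(64)))
  cors0 <- abs(cor(K0, U))
  expect_lt(mean(cors0), 0.1)

  seq1 <- generate_sequences(nodes, U, signal = 1,
                             seq_len_range = c(300L, 600L), seed = 5)
  K1 <- t(vapply(seq1, encode_rna_kmer, numeric(64)))
  # nodes with similar latents have more similar compositions than
  # dissimilar ones; quantify by correlation across random pairs
  set.seed(6)
  i <- sample(200, 400, TRUE); j <- sample(200, 400, TRUE)
  ok <- i != j
  lat_sim <- rowSums(U[i[ok], ] * U[j[ok], ])
  kv <- K1 / sqrt(rowSums(K1^2))
  kmer_sim <- rowSums(kv[i[ok], ] * kv[j[ok], ])
  expect_gt(cor(lat_sim, kmer_sim), 0.2)

  # lengths respect the configured bounds
  expect_true(all(nchar(seq0) >= 300 & nchar(seq0) <= 600))
})

test_that("protein sequences use the 20 standard residues", {
  ds <- small_dataset()
  prot <- ds$sequences[ds$network$nodes$node_type[
    match(names(ds$sequences), ds$network$nodes$node_id)] == "protein"]
  expect_true(all(grepl("^[ARNDCQEGHILKMFPSTWYV]+$", prot)))
  rna <- ds$sequences[!names(ds$sequences) %in% names(prot)]
  expect_true(all(grepl("^[ACGU]+$", rna)))
})

test_that("disease hierarchies give the documented similarity structure", {
  # depth 1: every disease on its own root, all similarities zero
  tab1 <- generate_disease_dag_forest(c("d1", "d2", "d3"), depth = 1,
                                      branching = 3, seed = 1)
  expect_equal(nrow(tab1), 3L)
  dags1 <- lapply(seq_len(3), function(i)
    build_disease_dag(tab1$node_id[i], tab1$tree_number[i]))
  expect_equal(disease_similarity(dags1[[1]], dags1[[2]]), 0)
  expect_equal(disease_similarity(dags1[[1]], dags1[[3]]), 0)

  # two children of one parent at delta = 0.5: similarity 1/3
  tab2 <- generate_disease_dag_forest(c("a", "b"), depth = 2, branching = 2,
                                      seed = 2)
  dags2 <- lapply(1:2, function(i)
    build_disease_dag(tab2$node_id[i], tab2$tree_number[i]))
  expect_equal(disease_similarity(dags2[[1]], dags2[[2]], delta = 0.5), 1 / 3)

  # deeper forests place every disease on a distinct leaf
  tab3 <- generate_disease_dag_forest(sprintf("d%02d", 1:20), depth = 3,
                                      branching = 3, seed = 3)
  expect_equal(nrow(tab3), 20L)
  expect_false(any(duplicated(tab3$tree_number)))
})

test_that("fingerprints are fair coins at zero signal and seeded", {
  U <- matrix(rnorm(120 * 8), 120, 8,
              dimnames = list(sprintf("dr%03d", 1:120), NULL))
  B0 <- generate_fingerprints(rownames(U), U, n_bits = 128, signal = 0,
                              seed = 4)
  expect_equal(dim(B0), c(120L, 128L))
  expect_true(all(B0 %in% c(0L, 1L)))
  expect_equal(mean(B0), 0.5, tolerance = 0.02)
  expect_identical(B0, generate_fingerprints(rownames(U), U, 128, 0, seed = 4))

  # strong signal: bits correlate with their latent projections
  B1 <- generate_fingerprints(rownames(U), U, n_bits = 128, signal = 1,
                              seed = 4)
  set.seed(4)
  W <- matrix(rnorm(128 * 8), 128, 8)
  proj <- tcrossprod(U, W)
  cors <- vapply(1:128, function(b) cor(B1[, b], proj[, b]), 0)
  expect_gt(mean(cors), 0.3)
})

test_that("written datasets reload through the standard readers", {
  ds <- small_dataset()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  suppressMessages(
    net <- read_edge_list(file.path(dir, "edges.tsv"),
                          node_meta = file.path(dir, "nodes.tsv")))
  expect_identical(net$edges, ds$network$edges)
  expect_identical(net$nodes, ds$network$nodes)
  Mk <- encode_fasta(file.path(dir, "rna.fasta"), "miRNA")
  expect_equal(ncol(Mk), 64L)
  dags <- read_mesh_table(file.path(dir, "mesh.tsv"))
  expect_setequal(names(dags),
                  ds$network$nodes$node_id[ds$network$nodes$node_type == "disease"])
  fp <- read_fingerprint_table(file.path(dir, "fingerprints.tsv"),
                               n_bits = ncol(ds$fingerprints))
  expect_equal(unname(fp), unname(ds$fingerprints[rownames(fp), ]))
})

test_that("attribute assembly covers every node with finite 64-dim rows", {
  ds <- small_dataset()
  at <- small_attributes()
  expect_equal(dim(at), c(nrow(ds$network$nodes), 64L))
  expect_true(all(is.finite(at)))
  expect_setequal(rownames(at), ds$network$nodes$node_id)
  # sequence nodes carry simplex rows; encoded nodes need not
  seq_ids <- ds$network$nodes$node_id[
    ds$network$nodes$node_type %in% c("miRNA", "lncRNA", "protein")]
  expect_equal(unname(rowSums(at[seq_ids, ])), rep(1, length(seq_ids)))
})
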