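test_that("edge lists are canonicalized, deduplicated and round-trip exactly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment",
               "mir1\tdis1\tmiRNA-disease",
               "mir1\tdis1\tmiRNA-disease",
               "dis2\tmir1\tmiRNA-disease"), f)
  expect_message(net <- read_edge_list(f), "dropped 1 duplicate")
  expect_equal(nrow(net$edges), 2L)
  expect_true(all(net$edges$head_index < net$edges$tail_index))
  # canonical order puts the lower global index first regardless of input order
  expect_setequal(net$edges$head_id, "mir1")  # miRNA sorts before disease

  g <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, g)
  net2 <- read_edge_list(g)
  expect_identical(net$edges, net2$edges)
  expect_identical(net$nodes, net2$nodes)
})

test_that("loader rejects malformed input with line numbers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mir1\tdis1\tmiRNA-disease", "a\tb\tnot-a-relation"), f)
  expect_error(read_edge_list(f), "line 2")
  writeLines("mir1 dis1 miRNA-disease", f)  # spaces, not tabs
  expect_error(read_edge_list(f), "line 1")
})

test_that("self-loops and conflicting node types are rejected", {
  expect_error(assoc_network(data.frame(head_id = "p1", tail_id = "p1",
                                        relation_type = "protein-protein")),
               "self-loop")
  e <- data.frame(head_id = c("x", "x"), tail_id = c("dis1", "pr1"),
                  relation_type = c("miRNA-disease", "lncRNA-protein"))
  expect_error(assoc_network(e), "conflicting types|do not match")
  # declared metadata contradicting the relation type
  expect_error(
    assoc_network(tiny_edges()[1, ],
                  nodes = data.frame(node_id = c("mirA", "disA"),
                                     node_type = c("drug", "disease"))),
    "do not match")
})

test_that("adjacency matrix is symmetric 0/1 with zero diagonal", {
  e2 <- data.frame(head_id = "m1", tail_id = "d1",
                   relation_type = "miRNA-disease")
  Y <- adjacency_matrix(assoc_network(e2), sparse = FALSE)
  expect_equal(unname(Y), matrix(c(0, 1, 1, 0), 2))

  tri <- data.frame(head_id = c("p1", "p2", "p3"),
                    tail_id = c("p2", "p3", "p1"),
                    relation_type = "protein-protein")
  Yt <- adjacency_matrix(assoc_network(tri))
  expect_equal(unname(Matrix::rowSums(Yt)), rep(2, 3))
  expect_true(Matrix::isSymmetric(Yt))
  expect_equal(sum(Yt), 2 * 3)

  # a pair linked under two relation types still contributes a single 1
  net <- small_dataset()$network
  expect_equal(sum(adjacency_matrix(net)) / 2,
               length(unique(paste(net$edges$head_index,
                                   net$edges$tail_index))))
})

test_that("declared isolated nodes are kept with dense 0-based indices", {
  net <- assoc_network(tiny_edges(),
                       nodes = data.frame(node_id = "lonely",
                                          node_type = "drug"))
  expect_true("lonely" %in% net$nodes$node_id)
  expect_identical(sort(net$nodes$global_index), 0:(nrow(net$nodes) - 1L))
})

test_that("negative sampling avoids positives, stratifies by type and reproduces", {
  net <- small_dataset()$network
  neg <- sample_negatives(net, seed = 7)
  expect_equal(nrow(neg), nrow(net$edges))
  expect_length(intersect(paste(neg$head_index, neg$tail_index),
                          paste(net$edges$head_index, net$edges$tail_index)),
                0L)
  expect_equal(table(neg$relation_type), table(net$edges$relation_type))
  expect_identical(sample_negatives(net, seed = 7), neg)
  expect_false(identical(sample_negatives(net, seed = 8), neg))
  # every negative respects the endpoint types of its relation
  rel <- relation_types()
  ty <- net$nodes$node_type[match(neg$head_id, net$nodes$node_id)]
  tz <- net$nodes$node_type[match(neg$tail_id, net$nodes$node_id)]
  m <- match(neg$relation_type, rel$relation)
  expect_true(all((ty == rel$type_a[m] & tz == rel$type_b[m]) |
                    (ty == rel$type_b[m] & tz == rel$type_a[m])))
})

test_that("negative sampling matches brute-force non-edge enumeration on small graphs", {
  ds <- small_dataset()
  net <- ds$network
  neg <- sample_negatives(net, count = 200L, seed = 3)
  # brute-force all legal non-edges, independently of the sampler
  rel <- relation_types()
  pos <- paste(net$edges$head_index, net$edges$tail_index)
  legal <- character(0)
  for (r in seq_len(nrow(rel))) {
    ia <- net$nodes$global_index[net$nodes$node_type == rel$type_a[r]]
    ib <- net$nodes$global_index[net$nodes$node_type == rel$type_b[r]]
    grid <- expand.grid(i = ia, j = ib)
    key <- paste(pmin(grid$i, grid$j), pmax(grid$i, grid$j))
    legal <- union(legal, setdiff(key[grid$i != grid$j], pos))
  }
  expect_true(all(paste(neg$head_index, neg$tail_index) %in% legal))
})

test_that("saturated relation-type pair space raises a named error", {
  # complete bipartite miRNA-disease block: no negatives left for the type
  e <- expand.grid(head_id = c("m1", "m2"), tail_id = c("d1", "d2"),
                   stringsAsFactors = FALSE)
  e$relation_type <- "miRNA-disease"
  net <- assoc_network(e)
  expect_error(sample_negatives(net, count = 1L, seed = 1),
               "insufficient negatives.*miRNA-disease")
})

test_that("fold splitting is balanced, exhaustive and label-stratified", {
  edges <- data.frame(head_index = 0:10, tail_index = 1:11,
                      label = rep(c(1, 0), c(6, 5)))
  fold <- split_folds(edges, k = 5, seed = 1)
  sizes <- tabulate(fold + 1L, nbins = 5)
  expect_equal(sum(sizes), 11L)
  expect_lte(max(sizes) - min(sizes), 1L)
  expect_setequal(fold, 0:4)
  # each label class spread evenly too
  for (lab in c(0, 1)) {
    cs <- tabulate(fold[edges$label == lab] + 1L, nbins = 5)
    expect_lte(max(cs) - min(cs), 1L)
  }
  expect_identical(split_folds(edges, 5, seed = 1), fold)
  expect_error(split_folds(edges[1:3, ], k = 5, seed = 1), "exceeds")
  expect_error(split_folds(edges, k = 1, seed = 1), ">= 2")
})

test_that("edge subsampling keeps the node set and exact complement", {
  net <- small_dataset()$network
  out <- subsample_edges(net, 0.8, seed = 9)
  expect_equal(nrow(out$train$edges), round(0.8 * nrow(net$edges)))
  expect_equal(nrow(out$train$edges) + nrow(out$held_out), nrow(net$edges))
  expect_identical(out$train$nodes, net$nodes)
  expect_length(intersect(paste(out$held_out$head_index, out$held_out$tail_index,
                                out$held_out$relation_type),
                          paste(out$train$edges$head_index,
                                out$train$edges$tail_index,
                                out$train$edges$relation_type)), 0L)
  expect_identical(subsample_edges(net, 0.8, seed = 9)$held_out, out$held_out)
  expect_error(subsample_edges(net, 1.2, seed = 1), "fraction")
})
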