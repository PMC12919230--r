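test_that("selected features are the deduplicated union of split features, in first-appearance order", {
  r1 <- tree_to_records(list(feature = "f1",
                             left = list(feature = "f3", left = NULL, right = NULL),
                             right = NULL), 0L)
  r2 <- tree_to_records(list(feature = "f3",
                             left = list(feature = "f9", left = NULL, right = NULL),
                             right = NULL), 1L)
  expect_equal(selected_features(rbind(r1, r2)), c("f1", "f3", "f9"))
  all_leaves <- tree_to_records(NULL, 0L)
  expect_equal(selected_features(all_leaves), character(0))
  dup <- do.call(rbind, lapply(0:99, function(t)
    tree_to_records(list(feature = "f0", left = NULL, right = NULL), t)))
  expect_equal(selected_features(dup), "f0")
})

test_that("graph edges are direct parent-child split pairs plus self-loops", {
  X <- dummy_omics(paste0("f", 0:9))
  # root f2, left child splits f5, right child leaf
  rec <- tree_to_records(list(feature = "f2",
                              left = list(feature = "f5", left = NULL, right = NULL),
                              right = NULL), 0L)
  g <- build_feature_graph(rec, 1L, X)
  expect_setequal(graph_edge_set(g), c("f2|f5", "f2|f2", "f5|f5"))
  expect_equal(g$nodes, c("f2", "f5"))
  s <- graph_stats(g)
  expect_equal(c(s$p_star, s$n_edges, s$edge_node_ratio), c(2, 3, 1.5))

  # (f0,f1) in one tree and (f1,f0) in another collapse to one edge
  ra <- tree_to_records(list(feature = "f0",
                             left = list(feature = "f1", left = NULL, right = NULL),
                             right = NULL), 0L)
  rb <- tree_to_records(list(feature = "f1",
                             left = list(feature = "f0", left = NULL, right = NULL),
                             right = NULL), 1L)
  g2 <- build_feature_graph(rbind(ra, rb), 1L, X)
  expect_setequal(graph_edge_set(g2), c("f0|f1", "f0|f0", "f1|f1"))

  # parent and child splitting the same feature add only the self-loop
  rc <- tree_to_records(list(feature = "f3",
                             left = list(feature = "f3", left = NULL, right = NULL),
                             right = NULL), 0L)
  g3 <- build_feature_graph(rc, 1L, X)
  expect_setequal(graph_edge_set(g3), "f3|f3")
  expect_equal(graph_stats(g3)$n_edges, 1L)

  expect_error(build_feature_graph(tree_to_records(NULL, 0L), 1L, X), "empty graph")
  bad <- tree_to_records(list(feature = "nope", left = NULL, right = NULL), 0L)
  expect_error(build_feature_graph(bad, 1L, X), "unknown feature")
})

test_that("graph construction matches the brute-force oracle on random toy ensembles", {
  feats <- paste0("g", 1:7)
  X <- dummy_omics(feats)
  set.seed(41)
  for (case in 1:10) {
    n_trees <- sample(1:3, 1)
    trees <- replicate(n_trees, random_toy_tree(feats, max_splits = 7),
                       simplify = FALSE)
    trees <- Filter(Negate(is.null), trees)
    if (length(trees) == 0L) next
    recs <- do.call(rbind, lapply(seq_along(trees), function(i)
      tree_to_records(trees[[i]], i - 1L)))
    g <- build_feature_graph(recs, 1L, X)
    expect_identical(graph_edge_set(g), oracle_edge_set(trees))
  }
})

test_that("union semantics: adding a tree never removes nodes or edges", {
  feats <- paste0("h", 1:6)
  X <- dummy_omics(feats)
  set.seed(17)
  trees <- list()
  prev_edges <- character(0)
  prev_nodes <- character(0)
  for (k in 1:5) {
    tr <- random_toy_tree(feats, max_splits = 5)
    if (is.null(tr)) next
    trees[[length(trees) + 1L]] <- tr
    recs <- do.call(rbind, lapply(seq_along(trees), function(i)
      tree_to_records(trees[[i]], i - 1L)))
    g <- build_feature_graph(recs, 1L, X)
    expect_true(all(prev_nodes %in% g$nodes))
    expect_true(all(prev_edges %in% graph_edge_set(g)))
    prev_nodes <- g$nodes
    prev_edges <- graph_edge_set(g)
    # structural invariants
    expect_true(all(g$adjacency %in% c(0, 1)))
    expect_identical(g$adjacency, t(g$adjacency))
    expect_true(all(diag(g$adjacency) == 1))
    expect_true(all(rowSums(g$adjacency) >= 1))
  }
})

test_that("graph stats handle self-loop-only and realistic edge densities", {
  feats <- paste0("s", 1:5)
  recs <- do.call(rbind, lapply(0:4, function(i)
    tree_to_records(list(feature = feats[i + 1], left = NULL, right = NULL), i)))
  g <- build_feature_graph(recs, 1L, dummy_omics(feats))
  s <- graph_stats(g)
  expect_equal(c(s$p_star, s$n_edges, s$edge_node_ratio), c(5, 5, 1))

  # 122 nodes carrying 260 edges (incl. self-loops) give ratio ~2.13,
  # the density scale observed for tree-derived omics graphs
  nodes <- sprintf("n%03d", 1:122)
  adj <- diag(122)
  set.seed(9)
  off <- 0L
  while (off < 138L) {
    ij <- sample(122, 2)
    if (adj[ij[1], ij[2]] == 0) {
      adj[ij[1], ij[2]] <- adj[ij[2], ij[1]] <- 1
      off <- off + 1L
    }
  }
  dimnames(adj) <- list(nodes, nodes)
  gg <- structure(list(modality_id = 1L, nodes = nodes,
                       edges = cbind(nodes, nodes), adjacency = adj,
                       col_map = 1:122),
                  class = "feature_graph")
  s2 <- graph_stats(gg)
  expect_equal(s2$n_edges, 260L)
  expect_equal(round(s2$edge_node_ratio, 2), 2.13)
})

test_that("fitted ensembles find separating features, are seeded, and reject bad input", {
  set.seed(31)
  n <- 60
  vals <- matrix(stats::runif(n * 10), n, 10,
                 dimnames = list(NULL, paste0("f", 1:10)))
  vals[, 7] <- rep(c(0, 1), length.out = n)  # perfectly separating binary feature
  y <- as.integer(vals[, 7] == 1)
  X <- omics_matrix(vals, feature_names = paste0("f", 1:10))
  rec <- fit_tree_ensemble(X, y, ensemble_spec("xgboost", 100, seed = 4))
  expect_true("f7" %in% selected_features(rec))
  rec2 <- fit_tree_ensemble(X, y, ensemble_spec("xgboost", 100, seed = 4))
  expect_identical(rec, rec2)

  rf_rec <- fit_tree_ensemble(X, y, ensemble_spec("random_forest", 50, seed = 4))
  expect_true(all(c("tree_index", "kind", "split_feature") %in% colnames(rf_rec)))
  expect_true("f7" %in% selected_features(rf_rec))
  g <- build_feature_graph(rf_rec, 2L, X)
  expect_true(all(diag(g$adjacency) == 1))

  expect_error(fit_tree_ensemble(X, rep(1L, n)), "class")
  Xbad <- X; Xbad$values[1, 1] <- Inf
  expect_error(fit_tree_ensemble(Xbad, y), "non-finite")
})

test_that("graphs export as edge-list TSV and GraphML", {
  feats <- paste0("e", 1:4)
  rec <- tree_to_records(list(feature = "e1",
                              left = list(feature = "e2", left = NULL, right = NULL),
                              right = list(feature = "e3", left = NULL, right = NULL)), 0L)
  g <- build_feature_graph(rec, 1L, dummy_omics(feats))
  tmp <- withr::local_tempdir()
  df <- export_feature_graph(g, file.path(tmp, "edges.tsv"),
                             file.path(tmp, "g.graphml"))
  expect_equal(sum(df$is_self_loop), 3)
  back <- utils::read.delim(file.path(tmp, "edges.tsv"))
  expect_equal(nrow(back), graph_stats(g)$n_edges)
  ig <- igraph::read_graph(file.path(tmp, "g.graphml"), format = "graphml")
  expect_equal(igraph::vcount(ig), 3)
})
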