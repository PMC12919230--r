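#' Specification of the per-modality tree ensemble
#'
#' @param method `"xgboost"` (gradient boosting, the default) or
#'   `"random_forest"` (used by the `motgnn_rf` ablation). Both backends feed
#'   the identical parser and graph builder.
#' @param n_trees Number of trees (boosting rounds / forest size).
#' @param seed Integer seed; together with single-threaded training this
#'   makes the fitted ensemble deterministic.
#' @param params Named list of extra hyperparameters passed verbatim to the
#'   backend (and recorded on the result); anything beyond the tree count
#'   follows the backend's defaults.
#' @return A list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(method = c("xgboost", "random_forest"),
                          n_trees = 100L, seed = 1L, params = list()) {
  method <- match.arg(method)
  n_trees <- as.integer(n_trees)
  if (n_trees < 1L) stop("'n_trees' must be >= 1", call. = FALSE)
  structure(list(method = method, n_trees = n_trees, seed = as.integer(seed),
                 params = params),
            class = "ensemble_spec")
}

empty_records <- function() {
  data.frame(tree_index = integer(0), node_id = integer(0),
             kind = character(0), split_feature = character(0),
             left_child = integer(0), right_child = integer(0),
             stringsAsFactors = FALSE)
}

#' Fit a supervised tree ensemble and parse its trees into node records
#'
#' Trains one binary classifier (gradient boosting or random forest) on a
#' single modality and flattens every tree into a table of node records:
#' split nodes carry the feature they test and their two children, leaves
#' carry neither. The records are the sole input of the downstream graph
#' builder, so both backends are interchangeable.
#'
#' @param X An [omics_matrix()] whose rows align with `y`.
#' @param y Integer 0/1 label vector; both classes must be present.
#' @param spec An [ensemble_spec()].
#' @return A data frame of node records with columns `tree_index` (0-based),
#'   `node_id`, `kind` (`"split"`/`"leaf"`), `split_feature`, `left_child`,
#'   `right_child`, ordered by `(tree_index, node_id)`.
#' @export
fit_tree_ensemble <- function(X, y, spec = ensemble_spec()) {
  stopifnot(inherits(X, "omics_matrix"), inherits(spec, "ensemble_spec"))
  y <- label_vector(y, n = nrow(X$values))
  if (any(!is.finite(X$values)))
    stop("non-finite values in 'X'", call. = FALSE)
  set.seed(spec$seed)
  if (spec$method == "xgboost") {
    params <- utils::modifyList(
      list(objective = "binary:logistic", nthread = 1L, seed = spec$seed),
      spec$params)
    dtrain <- xgboost::xgb.DMatrix(X$values, label = y, nthread = 1L)
    booster <- xgboost::xgb.train(params = params, data = dtrain,
                                  nrounds = spec$n_trees, verbose = 0)
    parse_xgb_trees(booster)
  } else {
    rf <- randomForest::randomForest(
      x = X$values, y = factor(y, levels = c(0L, 1L)),
      ntree = spec$n_trees)
    parse_rf_trees(rf, X$feature_names)
  }
}

# Flatten an xgboost booster dump into node records. IDs in the dump are
# "tree-node" strings; children are resolved back to integer node ids.
parse_xgb_trees <- function(booster) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  if (nrow(dt) == 0L) return(empty_records())
  node_of <- function(id) as.integer(sub("^\\d+-", "", id))
  is_leaf <- dt$Feature == "Leaf"
  out <- data.frame(
    tree_index = as.integer(dt$Tree),
    node_id = as.integer(dt$Node),
    kind = ifelse(is_leaf, "leaf", "split"),
    split_feature = ifelse(is_leaf, NA_character_, dt$Feature),
    left_child = ifelse(is_leaf, NA_integer_, node_of(dt$Yes)),
    right_child = ifelse(is_leaf, NA_integer_, node_of(dt$No)),
    stringsAsFactors = FALSE)
  out[order(out$tree_index, out$node_id), , drop = FALSE]
}

parse_rf_trees <- function(rf, feature_names) {
  recs <- lapply(seq_len(rf$ntree), function(k) {
    tr <- randomForest::getTree(rf, k, labelVar = FALSE)
    leaf <- tr[, "status"] == -1
    data.frame(
      tree_index = k - 1L,
      node_id = seq_len(nrow(tr)),
      kind = ifelse(leaf, "leaf", "split"),
      split_feature = ifelse(leaf, NA_character_,
                             feature_names[tr[, "split var"]]),
      left_child = ifelse(leaf, NA_integer_, as.integer(tr[, "left daughter"])),
      right_child = ifelse(leaf, NA_integer_, as.integer(tr[, "right daughter"])),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Features used anywhere in an ensemble
#'
#' The union, in first-appearance order over `(tree_index, node_id)`, of all
#' features tested at any split node. This union defines the reduced feature
#' space (size `p*`) and the node set of the feature graph.
#'
#' @param records Node records from [fit_tree_ensemble()].
#' @return Character vector of distinct feature names (possibly empty).
#' @export
selected_features <- function(records) {
  if (nrow(records) == 0L) return(character(0))
  records <- records[order(records$tree_index, records$node_id), , drop = FALSE]
  feats <- records$split_feature[records$kind == "split"]
  unique(feats)
}

#' Build an undirected feature graph from tree node records
#'
#' Every split node whose child is itself a split node contributes one
#' undirected edge between the two split features; edges into leaves
#' contribute nothing. Edges are unioned over all trees and deduplicated as
#' unordered pairs, then a self-loop is added for every selected feature so
#' each node keeps its own signal in the masked layer. The adjacency matrix
#' is binary and symmetric with a unit diagonal.
#'
#' @param records Node records from [fit_tree_ensemble()].
#' @param modality_id Modality index 1..3 stamped on the graph.
#' @param X The [omics_matrix()] the ensemble was trained on; used to check
#'   feature names and to record the original column index of each node.
#' @return An object of class `feature_graph`: list with `modality_id`,
#'   `nodes` (ordered selected features), `edges` (two-column character
#'   matrix of unordered pairs, self-loops included), `adjacency` (binary
#'   symmetric matrix with unit diagonal) and `col_map` (original column
#'   index per node).
#' @export
build_feature_graph <- function(records, modality_id, X) {
  stopifnot(inherits(X, "omics_matrix"))
  nodes <- selected_features(records)
  if (length(nodes) == 0L)
    stop("empty graph: no split features in the ensemble", call. = FALSE)
  unknown <- setdiff(nodes, X$feature_names)
  if (length(unknown) > 0L)
    stop(sprintf("unknown feature name(s) in records: %s",
                 paste(utils::head(unknown, 5), collapse = ", ")), call. = FALSE)
  records <- records[order(records$tree_index, records$node_id), , drop = FALSE]
  splits <- records[records$kind == "split", , drop = FALSE]

  pairs <- character(0)
  from <- character(0); to <- character(0)
  for (t in unique(splits$tree_index)) {
    tr <- splits[splits$tree_index == t, , drop = FALSE]
    feat_of <- stats::setNames(tr$split_feature, tr$node_id)
    for (r in seq_len(nrow(tr))) {
      for (child in c(tr$left_child[r], tr$right_child[r])) {
        cf <- feat_of[as.character(child)]
        if (!is.na(cf)) {  # child is a split node in the same tree
          a <- tr$split_feature[r]; b <- unname(cf)
          key <- paste(sort(c(a, b)), collapse = "\r")
          if (!(key %in% pairs)) {
            pairs <- c(pairs, key)
            from <- c(from, a); to <- c(to, b)
          }
        }
      }
    }
  }
  # drop any (f,f) split-pair, then add exactly one self-loop per node
  keep <- from != to
  from <- c(from[keep], nodes); to <- c(to[keep], nodes)

  p <- length(nodes)
  adjacency <- matrix(0, p, p, dimnames = list(nodes, nodes))
  fi <- match(from, nodes); ti <- match(to, nodes)
  adjacency[cbind(fi, ti)] <- 1
  adjacency[cbind(ti, fi)] <- 1
  diag(adjacency) <- 1

  edges <- cbind(feature_a = from, feature_b = to)
  structure(list(modality_id = as.integer(modality_id), nodes = nodes,
                 edges = edges, adjacency = adjacency,
                 col_map = match(nodes, X$feature_names)),
            class = "feature_graph")
}

#' @export
print.feature_graph <- function(x, ...) {
  s <- graph_stats(x)
  cat(sprintf("<feature_graph> modality %d: p*=%d nodes, %d edges (incl. self-loops), m=%.3f\n",
              x$modality_id, s$p_star, s$n_edges, s$edge_node_ratio))
  invisible(x)
}

#' Structural summary of a feature graph
#'
#' @param g A [build_feature_graph()] result.
#' @return List with `p_star` (node count), `n_edges` (unordered edges
#'   including self-loops, each counted once) and `edge_node_ratio`
#'   (`n_edges / p_star`, the sparsity summary of the graph).
#' @export
graph_stats <- function(g) {
  stopifnot(inherits(g, "feature_graph"))
  p <- length(g$nodes)
  a <- g$adjacency
  n_edges <- as.integer((sum(a) - p) / 2 + p)
  list(p_star = p, n_edges = n_edges, edge_node_ratio = n_edges / p)
}

#' Export a feature graph as edge-list TSV and GraphML
#'
#' @param g A `feature_graph`.
#' @param edge_tsv Path for the edge-list TSV
#'   (`feature_a`, `feature_b`, `is_self_loop`); `NULL` to skip.
#' @param graphml Path for a GraphML export via igraph; `NULL` to skip.
#' @return Invisibly, the edge-list data frame.
#' @export
export_feature_graph <- function(g, edge_tsv = NULL, graphml = NULL) {
  stopifnot(inherits(g, "feature_graph"))
  df <- data.frame(feature_a = g$edges[, 1], feature_b = g$edges[, 2],
                   is_self_loop = g$edges[, 1] == g$edges[, 2],
                   stringsAsFactors = FALSE)
  if (!is.null(edge_tsv))
    utils::write.table(df, edge_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml)) {
    ig <- igraph::graph_from_data_frame(df[, 1:2], directed = FALSE,
                                        vertices = g$nodes)
    igraph::write_graph(ig, graphml, format = "graphml")
  }
  invisible(df)
}
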