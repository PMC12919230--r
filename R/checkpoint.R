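# Model checkpoints are a directory with a single versioned JSON manifest
# holding config, graph structure (nodes, edges, col_map), all weight
# arrays and batch-norm running statistics. Text-only so checkpoints are
# portable and diffable.

serialize_array <- function(a) {
  if (is.matrix(a)) list(dim = dim(a), data = as.vector(a))
  else list(dim = NULL, data = as.vector(a))
}

deserialize_array <- function(s) {
  if (is.null(s$dim) || length(s$dim) == 0) as.numeric(s$data)
  else matrix(as.numeric(s$data), s$dim[1], s$dim[2])
}

#' Save / load a trained model checkpoint
#'
#' @param model A `motgnn_model`.
#' @param dir Checkpoint directory (created if missing).
#' @return `save_checkpoint` returns `dir` invisibly; `load_checkpoint`
#'   returns a `motgnn_model`.
#' @export
save_checkpoint <- function(model, dir) {
  stopifnot(inherits(model, "motgnn_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list(
    format = "motgnn-checkpoint",
    version = 1L,
    cfg = unclass(model$cfg),
    emb_widths = model$emb_widths,
    graphs = lapply(model$graphs, function(g) list(
      modality_id = g$modality_id, nodes = g$nodes,
      edges_a = g$edges[, 1], edges_b = g$edges[, 2],
      col_map = g$col_map)),
    params = lapply(model$params, serialize_array),
    bn_state = model$bn_state,
    history = as.list(model$history))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", dir, call. = FALSE)
  man <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(man$format, "motgnn-checkpoint"))
    stop("not a model checkpoint: ", dir, call. = FALSE)
  graphs <- lapply(man$graphs, function(g) {
    nodes <- g$nodes
    p <- length(nodes)
    adjacency <- matrix(0, p, p, dimnames = list(nodes, nodes))
    fi <- match(g$edges_a, nodes); ti <- match(g$edges_b, nodes)
    adjacency[cbind(fi, ti)] <- 1
    adjacency[cbind(ti, fi)] <- 1
    diag(adjacency) <- 1
    structure(list(modality_id = as.integer(g$modality_id), nodes = nodes,
                   edges = cbind(feature_a = g$edges_a, feature_b = g$edges_b),
                   adjacency = adjacency, col_map = as.integer(g$col_map)),
              class = "feature_graph")
  })
  bn <- lapply(man$bn_state, function(s)
    list(mean = as.numeric(s$mean), var = as.numeric(s$var)))
  structure(list(params = lapply(man$params, deserialize_array),
                 bn_state = bn,
                 graphs = graphs,
                 cfg = do.call(training_config, man$cfg),
                 emb_widths = as.integer(man$emb_widths),
                 history = as.data.frame(man$history)),
            class = "motgnn_model")
}

#' Write a per-epoch training log
#'
#' @param model A `motgnn_model` with a `history` element.
#' @param path Output TSV path (columns epoch, train_loss, val_loss, lr).
#' @export
write_training_log <- function(model, path) {
  utils::write.table(model$history, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
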