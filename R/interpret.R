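#' Connection-weights importance of input features
#'
#' The importance of feature `j` is the sum of the absolute values of the
#' masked input-layer weights on its row: `IF_j = sum_u |W_in[j,u]| *
#' 1(A[j,u] = 1)`. Positions outside the graph contribute exactly zero
#' regardless of their stored weight value.
#'
#' @param W_in `p*` x `p*` input weight matrix.
#' @param adjacency Binary `p*` x `p*` mask with unit diagonal.
#' @return Numeric vector of non-negative row scores.
#' @export
connection_weights <- function(W_in, adjacency) {
  if (!all(dim(W_in) == dim(adjacency)))
    stop("shape mismatch between W_in and adjacency", call. = FALSE)
  rowSums(abs(W_in * adjacency))
}

#' Per-feature importance of one modality of a trained model
#'
#' @param model A `motgnn_model`.
#' @param modality Modality index 1..3.
#' @return Named numeric vector of IF scores over the modality's graph
#'   nodes.
#' @export
feature_importance <- function(model, modality) {
  stopifnot(inherits(model, "motgnn_model"), modality %in% 1:3)
  g <- model$graphs[[modality]]
  stats::setNames(
    connection_weights(model$params[[sprintf("m%d_Win", modality)]],
                       g$adjacency),
    g$nodes)
}

#' Combine per-modality feature scores across modalities
#'
#' Features sharing an identical name across modalities have their scores
#' summed; names unique to one modality pass through. Since omics name
#' spaces are usually disjoint this typically concatenates the per-modality
#' scores, which remain the primary output.
#'
#' @param per_modality List of named numeric score vectors.
#' @return Named numeric vector sorted by score descending, ties broken by
#'   name ascending.
#' @export
aggregate_importance <- function(per_modality) {
  all_names <- unlist(lapply(per_modality, names), use.names = FALSE)
  all_scores <- unlist(per_modality, use.names = FALSE)
  combined <- tapply(all_scores, all_names, sum)
  combined <- stats::setNames(as.numeric(combined), names(combined))
  combined[order(-combined, names(combined))]
}

#' Relative importance of each omics graph
#'
#' `RIG_i = ||W_{Zi->f}||_1 / sum_k ||W_{Zk->f}||_1`, where `W_{Zi->f}` is
#' the block of fusion weights mapping modality `i`'s embedding into the
#' fusion layer and the L1 norm is the sum of absolute entries. The three
#' components sum to one.
#'
#' @param x A trained `motgnn_model`, or a list of three fusion weight
#'   matrices.
#' @return Numeric vector of length 3 summing to 1.
#' @export
graph_importance <- function(x) {
  blocks <- if (inherits(x, "motgnn_model")) {
    list(x$params$fuse_W1, x$params$fuse_W2, x$params$fuse_W3)
  } else if (is.list(x) && length(x) == 3L) {
    x
  } else stop("'x' must be a motgnn_model or a list of 3 matrices",
              call. = FALSE)
  norms <- vapply(blocks, function(w) sum(abs(w)), numeric(1))
  tot <- sum(norms)
  if (tot == 0) stop("degenerate fusion: all fusion weights are zero",
                     call. = FALSE)
  norms / tot
}

#' Full importance report for a trained model
#'
#' @param model A `motgnn_model`.
#' @return An object of class `importance_report`: list with
#'   `per_modality` (three named IF vectors), `combined` (cross-modality
#'   aggregated scores, sorted) and `graph_importance` (RIG, length 3,
#'   summing to 1).
#' @export
importance_report <- function(model) {
  per_modality <- lapply(1:3, function(i) feature_importance(model, i))
  structure(list(per_modality = per_modality,
                 combined = aggregate_importance(per_modality),
                 graph_importance = graph_importance(model)),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  rig <- x$graph_importance
  cat("<importance_report>\n")
  cat(sprintf("  relative graph importance: %.3f / %.3f / %.3f\n",
              rig[1], rig[2], rig[3]))
  top <- utils::head(x$combined, 5)
  cat("  top features:", paste(sprintf("%s (%.3g)", names(top), top),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Top-k ranked biomarkers
#'
#' @param report An [importance_report()].
#' @param k Number of features to return; must not exceed the number of
#'   scored features.
#' @return Character vector of the `k` highest-scoring feature names
#'   (score descending, ties by name ascending).
#' @export
top_k_biomarkers <- function(report, k) {
  stopifnot(inherits(report, "importance_report"))
  k <- as.integer(k)
  if (k < 1L || k > length(report$combined))
    stop(sprintf("k must be in 1..%d", length(report$combined)),
         call. = FALSE)
  sc <- report$combined
  names(sc)[order(-sc, names(sc))][seq_len(k)]
}

#' Write an importance report as TSV files
#'
#' Emits a long-format feature table (`modality`, `feature`, `IF`, `rank`)
#' and a one-row table of the relative graph importances.
#'
#' @param report An [importance_report()].
#' @param feature_tsv Path for the per-feature table; `NULL` to skip.
#' @param rig_tsv Path for the RIG row; `NULL` to skip.
#' @param top_k If not `NULL`, also print a grouped top-k summary per
#'   modality to the console.
#' @return Invisibly, the per-feature data frame.
#' @export
write_importance_tsv <- function(report, feature_tsv = NULL, rig_tsv = NULL,
                                 top_k = NULL) {
  rows <- lapply(1:3, function(i) {
    sc <- sort(report$per_modality[[i]], decreasing = TRUE)
    data.frame(modality = i, feature = names(sc), IF = as.numeric(sc),
               rank = seq_along(sc), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (!is.null(feature_tsv))
    utils::write.table(df, feature_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(rig_tsv)) {
    rig <- as.data.frame(as.list(stats::setNames(
      report$graph_importance, paste0("RIG_", 1:3))))
    utils::write.table(rig, rig_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(top_k)) {
    for (i in 1:3) {
      sc <- sort(report$per_modality[[i]], decreasing = TRUE)
      kk <- min(top_k, length(sc))
      cat(sprintf("modality %d top %d:\n  %s\n", i, kk,
                  paste(names(sc)[seq_len(kk)], collapse = ", ")))
    }
  }
  invisible(df)
}
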