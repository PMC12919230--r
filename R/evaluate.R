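#' Repeated stratified split scheme
#'
#' @param fractions Train/validation/test fractions; must sum to 1.
#' @param n_repeats Number of independent splits (default 20).
#' @param base_seed Integer; repeat `r` uses seed `base_seed + r`.
#' @return A list of class `split_scheme`.
#' @export
split_scheme <- function(fractions = c(0.6, 0.2, 0.2), n_repeats = 20L,
                         base_seed = 42L) {
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("'fractions' must be 3 positive numbers summing to 1", call. = FALSE)
  structure(list(fractions = fractions, n_repeats = as.integer(n_repeats),
                 base_seed = as.integer(base_seed)),
            class = "split_scheme")
}

# Largest-remainder allocation of nc items to the three fractions: floors
# first, then one extra item to the largest fractional remainders.
allocate_counts <- function(nc, fractions) {
  exact <- nc * fractions
  base <- floor(exact)
  rem <- nc - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test splits
#'
#' Each repeat partitions the samples into disjoint train, validation and
#' test sets covering all indices, allocating each class separately to the
#' three fractions by floor-plus-largest-remainder rounding so the class
#' ratio is preserved in every subset.
#'
#' @param y Integer 0/1 label vector.
#' @param scheme A [split_scheme()].
#' @return List of length `n_repeats`; each element is a list with integer
#'   index vectors `train`, `val`, `test`.
#' @export
stratified_splits <- function(y, scheme = split_scheme()) {
  y <- label_vector(y)
  if (min(table(y)) < 5L)
    stop("stratum too small: need at least 5 samples per class", call. = FALSE)
  lapply(seq_len(scheme$n_repeats), function(r) {
    set.seed(scheme$base_seed + r)
    sets <- list(train = integer(0), val = integer(0), test = integer(0))
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      cnt <- allocate_counts(length(idx), scheme$fractions)
      sets$train <- c(sets$train, idx[seq_len(cnt[1])])
      sets$val <- c(sets$val, idx[cnt[1] + seq_len(cnt[2])])
      sets$test <- c(sets$test, idx[cnt[1] + cnt[2] + seq_len(cnt[3])])
    }
    lapply(sets, sort)
  })
}

#' Classification metrics from probabilities
#'
#' Accuracy and F1 at a decision threshold, and ROC-AUC computed as the
#' rank statistic of the positive-class probabilities (tied scores receive
#' averaged ranks, so an uninformative constant score gives AUC 0.5).
#' F1 is defined as 0 when precision and recall are both 0.
#'
#' @param y_true Integer 0/1 vector containing both classes.
#' @param prob_positive Predicted positive-class probabilities in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return A list of class `metrics_record`: `accuracy`, `roc_auc`, `f1`,
#'   and confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
compute_metrics <- function(y_true, prob_positive, threshold = 0.5) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(prob_positive))
    stop("length mismatch between labels and probabilities", call. = FALSE)
  if (any(prob_positive < 0 | prob_positive > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (length(unique(y_true)) < 2L)
    stop("ROC-AUC undefined: only one class present in 'y_true'",
         call. = FALSE)
  pred <- as.integer(prob_positive >= threshold)
  tp <- sum(pred == 1L & y_true == 1L)
  fp <- sum(pred == 1L & y_true == 0L)
  tn <- sum(pred == 0L & y_true == 0L)
  fn <- sum(pred == 0L & y_true == 1L)
  accuracy <- (tp + tn) / length(y_true)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  r <- rank(prob_positive)
  n1 <- sum(y_true == 1L); n0 <- sum(y_true == 0L)
  roc_auc <- (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(accuracy = accuracy, roc_auc = roc_auc, f1 = f1,
                 tp = tp, fp = fp, tn = tn, fn = fn),
            class = "metrics_record")
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf("accuracy %.4f | ROC-AUC %.4f | F1 %.4f (TP %d FP %d TN %d FN %d)\n",
              x$accuracy, x$roc_auc, x$f1, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

subset_omics <- function(x, idx) {
  omics_matrix(x$values[idx, , drop = FALSE], x$sample_ids[idx],
               x$feature_names, x$modality_id)
}

#' Run the full pipeline over repeated stratified splits
#'
#' For every repeat: normalize each modality (min-max fitted on the
#' training split by default), fit one tree ensemble per modality on the
#' training split, convert the ensembles into feature graphs, train the
#' fused graph-embedded classifier with early stopping on the validation
#' split, and evaluate on the held-out test split. Reports per-repeat
#' metrics, their mean, SD and normal-approximation 95% confidence
#' interval, per-repeat graph statistics, and importance reports with the
#' averaged relative graph importance.
#'
#' @param data Either a [synthetic_config()] (data are generated first) or
#'   a list with `matrices` (three [omics_matrix()]) and `labels` (0/1).
#' @param model `"motgnn"` (gradient-boosted graphs) or `"motgnn_rf"`
#'   (random-forest graphs); the two differ only in the ensemble method.
#' @param cfg A [training_config()]; its seed is re-derived per repeat from
#'   the scheme's base seed.
#' @param scheme A [split_scheme()].
#' @param n_trees Trees per ensemble (default 100).
#' @param normalize `"per_split"` (fit min-max on the training split only;
#'   leakage-safe default) or `"whole_dataset"` (scale the full matrix
#'   before splitting).
#' @param graph_scope `"per_split"` (rebuild ensembles and graphs inside
#'   every repeat; leakage-safe default) or `"whole_dataset"` (build one
#'   set of graphs from all samples and reuse it across repeats).
#' @param threshold Decision threshold for the positive class.
#' @param outdir If not `NULL`, write metrics, graph-stats and importance
#'   TSVs, a config echo, the last repeat's training log and a model
#'   checkpoint into this directory.
#' @return An object of class `motgnn_experiment`: list with `per_repeat`
#'   (data frame), `summary` (per-repeat rows plus one aggregate mean row),
#'   `aggregate` (mean/sd/CI per metric), `rig_mean`, `importance` (list of
#'   per-repeat [importance_report()]s) and `last_model`.
#' @export
run_experiment <- function(data, model = c("motgnn", "motgnn_rf"),
                           cfg = training_config(), scheme = split_scheme(),
                           n_trees = 100L,
                           normalize = c("per_split", "whole_dataset"),
                           graph_scope = c("per_split", "whole_dataset"),
                           threshold = 0.5, outdir = NULL) {
  model <- match.arg(model)
  normalize <- match.arg(normalize)
  graph_scope <- match.arg(graph_scope)
  method <- if (model == "motgnn") "xgboost" else "random_forest"
  if (inherits(data, "synthetic_config")) data <- generate_multiomics(data)
  mats <- data$matrices
  y <- label_vector(data$labels, n = nrow(mats[[1]]$values))
  splits <- stratified_splits(y, scheme)

  if (normalize == "whole_dataset")
    mats <- lapply(mats, function(x) minmax_normalize(x))
  full_graphs <- NULL
  if (graph_scope == "whole_dataset") {
    full_mats <- if (normalize == "whole_dataset") mats
                 else lapply(mats, function(x) minmax_normalize(x))
    full_graphs <- lapply(1:3, function(i) {
      spec <- ensemble_spec(method, n_trees, seed = scheme$base_seed)
      rec <- fit_tree_ensemble(full_mats[[i]], y, spec)
      build_feature_graph(rec, i, full_mats[[i]])
    })
  }

  rows <- list(); reports <- list(); gstat_rows <- list()
  last_model <- NULL
  for (r in seq_len(scheme$n_repeats)) {
    sp <- splits[[r]]
    seed_r <- scheme$base_seed + r
    tr <- lapply(mats, subset_omics, idx = sp$train)
    va <- lapply(mats, subset_omics, idx = sp$val)
    te <- lapply(mats, subset_omics, idx = sp$test)
    if (normalize == "per_split") {
      va <- Map(minmax_normalize, tr, va)
      te <- Map(minmax_normalize, tr, te)
      tr <- lapply(tr, minmax_normalize)
    }
    graphs <- if (!is.null(full_graphs)) full_graphs else
      lapply(1:3, function(i) {
        spec <- ensemble_spec(method, n_trees, seed = seed_r)
        rec <- fit_tree_ensemble(tr[[i]], y[sp$train], spec)
        build_feature_graph(rec, i, tr[[i]])
      })
    cfg_r <- cfg
    cfg_r$seed <- seed_r
    fit <- tryCatch(
      train_motgnn(tr, y[sp$train], graphs, cfg_r, va, y[sp$val]),
      error = function(e) stop(sprintf("repeat %d: %s", r, conditionMessage(e)),
                               call. = FALSE))
    prob <- predict(fit, te)
    met <- compute_metrics(y[sp$test], prob[, "p1"], threshold)
    rep_i <- importance_report(fit)
    gs <- lapply(graphs, graph_stats)
    rows[[r]] <- data.frame(
      repeat_index = r, accuracy = met$accuracy, roc_auc = met$roc_auc,
      f1 = met$f1, tp = met$tp, fp = met$fp, tn = met$tn, fn = met$fn,
      rig_1 = rep_i$graph_importance[1], rig_2 = rep_i$graph_importance[2],
      rig_3 = rep_i$graph_importance[3],
      epochs_trained = nrow(fit$history))
    gstat_rows[[r]] <- do.call(rbind, lapply(1:3, function(i)
      data.frame(repeat_index = r, modality = i, p_star = gs[[i]]$p_star,
                 n_edges = gs[[i]]$n_edges,
                 edge_node_ratio = gs[[i]]$edge_node_ratio)))
    reports[[r]] <- rep_i
    last_model <- fit
  }
  per_repeat <- do.call(rbind, rows)
  gstats <- do.call(rbind, gstat_rows)
  metric_cols <- c("accuracy", "roc_auc", "f1")
  means <- colMeans(per_repeat[, metric_cols, drop = FALSE])
  sds <- apply(per_repeat[, metric_cols, drop = FALSE], 2L, stats::sd)
  half <- 1.96 * sds / sqrt(scheme$n_repeats)
  aggregate <- data.frame(metric = metric_cols, mean = as.numeric(means),
                          sd = as.numeric(sds),
                          ci_lower = as.numeric(means - half),
                          ci_upper = as.numeric(means + half))
  mean_row <- per_repeat[1, ]
  mean_row[1, ] <- NA
  num_cols <- names(per_repeat)[vapply(per_repeat, is.numeric, logical(1))]
  mean_row[1, num_cols] <- colMeans(per_repeat[, num_cols, drop = FALSE])
  mean_row$repeat_index <- NA_integer_
  summary_tab <- rbind(per_repeat, mean_row)
  rownames(summary_tab) <- c(seq_len(scheme$n_repeats), "aggregate")
  rig_mean <- colMeans(per_repeat[, c("rig_1", "rig_2", "rig_3")])

  out <- structure(list(model = model, per_repeat = per_repeat,
                        summary = summary_tab, aggregate = aggregate,
                        graph_stats = gstats, rig_mean = as.numeric(rig_mean),
                        importance = reports, last_model = last_model,
                        scheme = scheme, cfg = cfg, n_trees = n_trees,
                        normalize = normalize, graph_scope = graph_scope),
                   class = "motgnn_experiment")
  if (!is.null(outdir)) write_experiment(out, outdir)
  out
}

#' @export
print.motgnn_experiment <- function(x, ...) {
  cat(sprintf("<motgnn_experiment> %s, %d repeats\n", x$model,
              x$scheme$n_repeats))
  for (i in seq_len(nrow(x$aggregate)))
    cat(sprintf("  %-8s %.3f +/- %.3f [%.3f, %.3f]\n",
                x$aggregate$metric[i], x$aggregate$mean[i], x$aggregate$sd[i],
                x$aggregate$ci_lower[i], x$aggregate$ci_upper[i]))
  cat(sprintf("  mean RIG: %.3f / %.3f / %.3f\n",
              x$rig_mean[1], x$rig_mean[2], x$rig_mean[3]))
  invisible(x)
}

#' Write the output files of an experiment
#'
#' @param x A `motgnn_experiment`.
#' @param outdir Output directory (created if missing): `metrics.tsv`
#'   (per repeat plus aggregate row), `aggregate.tsv`, `graph_stats.tsv`,
#'   `importance.tsv` and `rig.tsv` (last repeat / mean), `config.yaml`
#'   echo, `training_log.tsv` and a `checkpoint/` directory for the last
#'   repeat's model.
#' @return `outdir`, invisibly.
#' @export
write_experiment <- function(x, outdir) {
  stopifnot(inherits(x, "motgnn_experiment"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  w <- function(df, f) utils::write.table(
    df, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(x$summary, "metrics.tsv")
  w(x$aggregate, "aggregate.tsv")
  w(x$graph_stats, "graph_stats.tsv")
  last_rep <- x$importance[[length(x$importance)]]
  write_importance_tsv(last_rep, file.path(outdir, "importance.tsv"),
                       file.path(outdir, "rig.tsv"))
  cfg_echo <- list(model = x$model, n_trees = x$n_trees,
                   normalize = x$normalize, graph_scope = x$graph_scope,
                   training = unclass(x$cfg), scheme = unclass(x$scheme))
  yaml::write_yaml(cfg_echo, file.path(outdir, "config.yaml"))
  write_training_log(x$last_model, file.path(outdir, "training_log.tsv"))
  save_checkpoint(x$last_model, file.path(outdir, "checkpoint"))
  invisible(outdir)
}
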