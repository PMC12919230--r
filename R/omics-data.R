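#' Construct an omics matrix
#'
#' A light container for one modality's samples-by-features matrix together
#' with sample identifiers, feature names and a modality index. All
#' downstream stages (graph construction, encoding, evaluation) consume this
#' class.
#'
#' @param values Numeric matrix, samples in rows, features in columns. Must
#'   be free of missing and non-finite values.
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   row. Defaults to existing rownames or `sample_1 ... sample_n`.
#' @param feature_names Character vector of unique feature names, one per
#'   column. Defaults to existing colnames.
#' @param modality_id Integer in 1..3 identifying the omics layer.
#' @return An object of class `omics_matrix`: a list with elements `values`
#'   (the matrix with dimnames set), `sample_ids`, `feature_names` and
#'   `modality_id`.
#' @export
omics_matrix <- function(values, sample_ids = NULL, feature_names = NULL,
                         modality_id = 1L) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("'values' contains missing or non-finite entries", call. = FALSE)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(values)))
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(values)
    if (is.null(feature_names))
      stop("'feature_names' must be supplied when 'values' has no colnames",
           call. = FALSE)
  }
  if (length(sample_ids) != nrow(values))
    stop("length of 'sample_ids' does not match row count", call. = FALSE)
  if (length(feature_names) != ncol(values))
    stop("length of 'feature_names' does not match column count", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("'sample_ids' must be unique", call. = FALSE)
  if (anyDuplicated(feature_names)) stop("'feature_names' must be unique", call. = FALSE)
  modality_id <- as.integer(modality_id)
  if (!modality_id %in% 1:3)
    stop("'modality_id' must be 1, 2 or 3", call. = FALSE)
  dimnames(values) <- list(sample_ids, feature_names)
  structure(list(values = values, sample_ids = sample_ids,
                 feature_names = feature_names, modality_id = modality_id),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> modality %d: %d samples x %d features\n",
              x$modality_id, nrow(x$values), ncol(x$values)))
  cat(sprintf("  value range: [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Validate a binary label vector
#'
#' @param labels Vector coercible to integer 0/1, aligned to the sample rows
#'   of the omics matrices.
#' @param n Expected length (optional).
#' @return Integer vector of 0/1 values.
#' @export
label_vector <- function(labels, n = NULL) {
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("labels must be 0/1 with no missing values", call. = FALSE)
  if (!is.null(n) && length(labels) != n)
    stop(sprintf("expected %d labels, got %d", n, length(labels)), call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in the label vector", call. = FALSE)
  labels
}

#' Configuration for the synthetic multi-omics generator
#'
#' Defines the study conditions under which synthetic three-modality data are
#' drawn: sample size, class ratio, per-modality dimensionality and number of
#' informative (signal-carrying) features, the between-class mean shift
#' applied to informative features, the additive noise level, and the
#' marginal style of each modality.
#'
#' @param n_samples Number of samples.
#' @param class_ratio Fraction of positive (label 1) samples, in (0,1). The
#'   positive count is `round(n_samples * class_ratio)` with ties rounded
#'   half up.
#' @param dims Integer vector of length 3: feature counts per modality.
#' @param informative_per_modality Integer vector of length 3: how many
#'   features in each modality carry class signal.
#' @param effect_size Non-negative mean shift (pre-noise, on the raw scale of
#'   each modality style) between the classes for informative features.
#'   A scalar is recycled across modalities; a length-3 vector sets the shift
#'   per modality (0 turns signal off in that modality).
#' @param noise_sd Standard deviation of i.i.d. Gaussian noise added to every
#'   entry.
#' @param modality_styles Character vector of length 3 drawn from
#'   `"bimodal"` (methylation-like beta-mixture), `"right_skewed"`
#'   (expression-like exponential) and `"sparse"` (miRNA-like zero-inflated
#'   positive tail).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 200L,
                             class_ratio = 0.5,
                             dims = c(100L, 100L, 40L),
                             informative_per_modality = c(10L, 10L, 5L),
                             effect_size = 1.0,
                             noise_sd = 0.5,
                             modality_styles = c("bimodal", "right_skewed", "sparse"),
                             seed = 1L) {
  n_samples <- as.integer(n_samples)
  dims <- as.integer(dims)
  informative_per_modality <- as.integer(informative_per_modality)
  if (length(effect_size) == 1L) effect_size <- rep(effect_size, 3L)
  if (n_samples < 10L)
    stop("invalid 'n_samples': need at least 10 samples", call. = FALSE)
  if (!is.numeric(class_ratio) || class_ratio <= 0 || class_ratio >= 1)
    stop("invalid 'class_ratio': must lie strictly between 0 and 1", call. = FALSE)
  if (n_samples * min(class_ratio, 1 - class_ratio) < 5)
    stop("invalid 'class_ratio': minority stratum would have fewer than 5 samples",
         call. = FALSE)
  if (length(dims) != 3L || any(dims < 1L))
    stop("invalid 'dims': need 3 positive feature counts", call. = FALSE)
  if (length(informative_per_modality) != 3L || any(informative_per_modality < 0L))
    stop("invalid 'informative_per_modality': need 3 non-negative counts", call. = FALSE)
  if (any(informative_per_modality > dims))
    stop("invalid 'informative_per_modality': exceeds 'dims' for some modality",
         call. = FALSE)
  if (length(effect_size) != 3L || any(effect_size < 0))
    stop("invalid 'effect_size': must be non-negative (scalar or length 3)",
         call. = FALSE)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("invalid 'noise_sd': must be a non-negative scalar", call. = FALSE)
  styles <- match.arg(modality_styles,
                      c("bimodal", "right_skewed", "sparse"),
                      several.ok = TRUE)
  if (length(styles) != 3L)
    stop("invalid 'modality_styles': need 3 style tags", call. = FALSE)
  structure(list(n_samples = n_samples, class_ratio = class_ratio, dims = dims,
                 informative_per_modality = informative_per_modality,
                 effect_size = effect_size, noise_sd = noise_sd,
                 modality_styles = styles, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Raw draws for one modality style, n x p. Styles mirror the marginal
# heterogeneity of methylation (bimodal in [0,1]), expression (right-skewed
# positive) and miRNA (zero-inflated positive) layers.
draw_style <- function(style, n, p) {
  m <- n * p
  x <- switch(style,
    bimodal = {
      lo <- stats::rbeta(m, 2, 8)
      hi <- stats::rbeta(m, 8, 2)
      pick <- stats::runif(m) < 0.5
      ifelse(pick, hi, lo)
    },
    right_skewed = stats::rexp(m, rate = 1),
    sparse = {
      tail <- stats::rexp(m, rate = 1)
      nz <- stats::runif(m) < 0.5
      ifelse(nz, tail, 0)
    })
  matrix(x, n, p)
}

#' Generate synthetic multi-omics data with planted signal
#'
#' Draws three heterogeneous modality matrices on a shared set of samples,
#' with a controllable class ratio and a planted subset of informative
#' features per modality. Informative features receive an additive mean
#' shift of `effect_size` for positive-class samples before Gaussian noise
#' is added; all remaining features are class-independent. The returned
#' values are raw (unscaled); min-max normalization is applied downstream,
#' per training split, by the evaluation harness (see
#' [minmax_normalize()]).
#'
#' @param config A [synthetic_config()] object.
#' @return A list with elements `matrices` (list of three [omics_matrix()]
#'   objects), `labels` (integer 0/1 vector aligned to sample order) and
#'   `informative` (list of three character vectors naming the planted
#'   informative features per modality, for test harnesses).
#' @export
generate_multiomics <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  set.seed(config$seed)
  n <- config$n_samples
  n_pos <- as.integer(floor(n * config$class_ratio + 0.5))  # round half up
  labels <- c(rep(1L, n_pos), rep(0L, n - n_pos))
  labels <- labels[sample.int(n)]
  sample_ids <- sprintf("S%03d", seq_len(n))
  prefixes <- c("meth", "mrna", "mirna")
  matrices <- vector("list", 3L)
  informative <- vector("list", 3L)
  for (i in 1:3) {
    p <- config$dims[i]
    vals <- draw_style(config$modality_styles[i], n, p)
    k <- config$informative_per_modality[i]
    feats <- sprintf("%s_f%04d", prefixes[i], seq_len(p))
    inf_idx <- if (k > 0) seq_len(k) else integer(0)
    if (k > 0 && config$effect_size[i] > 0) {
      vals[labels == 1L, inf_idx] <- vals[labels == 1L, inf_idx] +
        config$effect_size[i]
    }
    if (config$noise_sd > 0)
      vals <- vals + matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)
    matrices[[i]] <- omics_matrix(vals, sample_ids, feats, modality_id = i)
    informative[[i]] <- feats[inf_idx]
  }
  list(matrices = matrices, labels = labels, informative = informative)
}

#' Min-max normalization fitted on one matrix, applied to another
#'
#' Per-feature scaling `(x - min_train) / (max_train - min_train)` with the
#' minima and maxima taken from `train`. Features that are constant in
#' `train` map to 0; outputs are clipped to `[0, 1]` so unseen values outside
#' the training range cannot escape the unit interval.
#'
#' @param train An [omics_matrix()] supplying the per-feature ranges.
#' @param apply_to An [omics_matrix()] to transform; defaults to `train`
#'   itself. Its feature names must equal those of `train`, in order.
#' @return An [omics_matrix()] with values in `[0, 1]`.
#' @export
minmax_normalize <- function(train, apply_to = train) {
  stopifnot(inherits(train, "omics_matrix"), inherits(apply_to, "omics_matrix"))
  if (!identical(train$feature_names, apply_to$feature_names))
    stop("feature names of 'apply_to' do not align with 'train'", call. = FALSE)
  mins <- apply(train$values, 2L, min)
  maxs <- apply(train$values, 2L, max)
  rng <- maxs - mins
  out <- sweep(apply_to$values, 2L, mins, "-")
  nonconst <- rng > 0
  out[, nonconst] <- sweep(out[, nonconst, drop = FALSE], 2L,
                           rng[nonconst], "/")
  out[, !nonconst] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  omics_matrix(out, apply_to$sample_ids, apply_to$feature_names,
               apply_to$modality_id)
}

#' Write / read omics matrices and labels as delimited text
#'
#' Matrices are stored as TSV with a `sample_id` first column and feature
#' names in the header; labels as a two-column TSV `(sample_id, label)`.
#'
#' @param x An [omics_matrix()].
#' @param path Output file path.
#' @return `write_omics_tsv` returns `path` invisibly; `read_omics_tsv`
#'   returns an [omics_matrix()].
#' @export
write_omics_tsv <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  df <- data.frame(sample_id = x$sample_ids, x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_omics_tsv
#' @param modality_id Modality index recorded on the matrix read back in.
#' @export
read_omics_tsv <- function(path, modality_id = 1L) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df)[1])
    stop("first column of an omics TSV must be 'sample_id'", call. = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  omics_matrix(vals, as.character(df[[1]]), colnames(df)[-1], modality_id)
}

#' @rdname write_omics_tsv
#' @param labels Integer 0/1 vector.
#' @param sample_ids Sample identifiers aligned to `labels`.
#' @export
write_labels_tsv <- function(labels, sample_ids, path) {
  utils::write.table(data.frame(sample_id = sample_ids, label = labels),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_omics_tsv
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(label_vector(df$label), as.character(df$sample_id))
}
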