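#' Training configuration for the fused graph-embedded classifier
#'
#' Defaults are the selected values of the model's tuning grid: learning
#' rate 1e-4, batch size 16, up to 500 epochs, dropout 0.5, L2 coefficient
#' 0.01, early-stopping patience 10 with min delta 0.001. `depth`/`width`
#' size the per-modality dense stack that follows the graph-embedded layer;
#' `fusion_width` sizes the hidden layer of the cross-omics classifier.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param epochs Maximum number of epochs.
#' @param dropout Dropout probability in `[0, 1)` applied after each hidden
#'   dense layer during training.
#' @param l2_lambda Coefficient of the L2 penalty on the weight matrices
#'   (biases and batch-norm parameters are not penalized; the masked input
#'   matrix is penalized through its effective, mask-multiplied weights).
#' @param patience Number of consecutive epochs without a validation-loss
#'   improvement of at least `min_delta` before training stops.
#' @param min_delta Minimum decrease of validation loss that counts as an
#'   improvement.
#' @param depth Number of dense layers per modality encoder after the
#'   graph-embedded layer (0 keeps the masked layer output as the embedding).
#' @param width Units per dense encoder layer.
#' @param fusion_width Units in the fusion hidden layer.
#' @param seed Integer seed driving weight initialization, batch shuffling
#'   and dropout masks.
#' @return A list of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-4, batch_size = 16L,
                            epochs = 500L, dropout = 0.5, l2_lambda = 0.01,
                            patience = 10L, min_delta = 0.001,
                            depth = 1L, width = 64L, fusion_width = 64L,
                            seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1,
            dropout >= 0, dropout < 1, l2_lambda >= 0,
            patience >= 1, min_delta >= 0, depth >= 0, width >= 1,
            fusion_width >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), dropout = dropout,
                 l2_lambda = l2_lambda, patience = as.integer(patience),
                 min_delta = min_delta, depth = as.integer(depth),
                 width = as.integer(width),
                 fusion_width = as.integer(fusion_width),
                 seed = as.integer(seed)),
            class = "training_config")
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Graph-embedded forward pass
#'
#' The defining layer of the model: a dense layer whose input weight matrix
#' is element-wise multiplied by the augmented adjacency before the product,
#' `sigma(X (W %o% A) + b)`, so only graph-supported connections between
#' input features and first-layer units are ever active.
#'
#' @param Xstar Samples-by-`p*` input matrix (reduced feature space).
#' @param adjacency `p*` x `p*` binary symmetric matrix with unit diagonal.
#' @param W_in `p*` x `p*` weight matrix.
#' @param b_in Length-`p*` bias vector, broadcast over samples.
#' @param activation `"relu"` (default) or `"identity"`.
#' @return Samples-by-`p*` activation matrix.
#' @export
graph_embedded_forward <- function(Xstar, adjacency, W_in, b_in,
                                   activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  p <- ncol(Xstar)
  if (!all(dim(adjacency) == c(p, p)) || !all(dim(W_in) == c(p, p)))
    stop("shape mismatch: adjacency and W_in must be p* x p*", call. = FALSE)
  if (length(b_in) != p)
    stop("shape mismatch: b_in must have length p*", call. = FALSE)
  out <- sweep(Xstar %*% (W_in * adjacency), 2L, b_in, "+")
  if (activation == "relu") relu(out) else out
}

#' Binary cross-entropy loss
#'
#' `-(1/n) * sum(y*log(p) + (1-y)*log(1-p))` on the positive-class
#' probability, with `p` clipped to `[eps, 1-eps]` so the loss is finite for
#' degenerate probabilities.
#'
#' @param y Integer 0/1 vector.
#' @param p Predicted positive-class probabilities, same length as `y`.
#' @param eps Clipping constant (default 1e-7).
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(y, p, eps = 1e-7) {
  if (length(y) != length(p))
    stop("'y' and 'p' have different lengths", call. = FALSE)
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

bn_eps <- 1e-5

# ---- parameter initialization -------------------------------------------

init_params <- function(graphs, cfg) {
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
  params <- list(); bn <- list()
  emb <- integer(3)
  for (i in 1:3) {
    p <- length(graphs[[i]]$nodes)
    params[[sprintf("m%d_Win", i)]] <- he(p, p)
    params[[sprintf("m%d_bin", i)]] <- rep(0, p)
    d_in <- p
    if (cfg$depth > 0) {
      for (l in seq_len(cfg$depth)) {
        params[[sprintf("m%d_l%d_W", i, l)]] <- he(d_in, cfg$width)
        params[[sprintf("m%d_l%d_b", i, l)]] <- rep(0, cfg$width)
        params[[sprintf("m%d_l%d_gamma", i, l)]] <- rep(1, cfg$width)
        params[[sprintf("m%d_l%d_beta", i, l)]] <- rep(0, cfg$width)
        bn[[sprintf("m%d_l%d", i, l)]] <- list(mean = rep(0, cfg$width),
                                               var = rep(1, cfg$width))
        d_in <- cfg$width
      }
    }
    emb[i] <- d_in
  }
  for (i in 1:3)
    params[[sprintf("fuse_W%d", i)]] <- he(emb[i], cfg$fusion_width)
  params[["fuse_b"]] <- rep(0, cfg$fusion_width)
  params[["fuse_gamma"]] <- rep(1, cfg$fusion_width)
  params[["fuse_beta"]] <- rep(0, cfg$fusion_width)
  bn[["fuse"]] <- list(mean = rep(0, cfg$fusion_width),
                       var = rep(1, cfg$fusion_width))
  params[["out_W"]] <- he(cfg$fusion_width, 2L)
  params[["out_b"]] <- rep(0, 2L)
  list(params = params, bn_state = bn, emb_widths = emb)
}

# ---- forward / backward --------------------------------------------------

bn_forward <- function(x, gamma, beta, state, train) {
  if (train) {
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2L, mu, "-")^2)
  } else {
    mu <- state$mean; v <- state$var
  }
  istd <- 1 / sqrt(v + bn_eps)
  xhat <- sweep(sweep(x, 2L, mu, "-"), 2L, istd, "*")
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = out, xhat = xhat, istd = istd, mu = mu, var = v)
}

bn_backward <- function(dy, cache, gamma) {
  m <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, gamma, "*")
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dx <- sweep(m * dxhat - matrix(s1, m, length(s1), byrow = TRUE) -
                cache$xhat * matrix(s2, m, length(s2), byrow = TRUE),
              2L, cache$istd / m, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# One full forward pass over all modalities + fusion. Xs is a list of three
# reduced (samples x p*_i) matrices. Returns probabilities and, in train
# mode, the caches needed for backprop. BN running stats are updated in
# train mode (momentum 0.9) and used as-is in eval mode.
model_forward <- function(params, bn_state, graphs, cfg, Xs, train = FALSE) {
  caches <- list(modality = vector("list", 3L))
  Z <- vector("list", 3L)
  momentum <- 0.9
  for (i in 1:3) {
    A <- graphs[[i]]$adjacency
    Win <- params[[sprintf("m%d_Win", i)]]
    bin <- params[[sprintf("m%d_bin", i)]]
    S0 <- sweep(Xs[[i]] %*% (Win * A), 2L, bin, "+")
    H <- relu(S0)
    mc <- list(X = Xs[[i]], S0 = S0, layers = list())
    if (cfg$depth > 0) {
      for (l in seq_len(cfg$depth)) {
        key <- sprintf("m%d_l%d", i, l)
        W <- params[[paste0(key, "_W")]]; b <- params[[paste0(key, "_b")]]
        gamma <- params[[paste0(key, "_gamma")]]
        beta <- params[[paste0(key, "_beta")]]
        Hin <- H
        S <- sweep(Hin %*% W, 2L, b, "+")
        bnc <- bn_forward(S, gamma, beta, bn_state[[key]], train)
        if (train) {
          bn_state[[key]]$mean <- momentum * bn_state[[key]]$mean +
            (1 - momentum) * bnc$mu
          bn_state[[key]]$var <- momentum * bn_state[[key]]$var +
            (1 - momentum) * bnc$var
        }
        R <- relu(bnc$out)
        if (train && cfg$dropout > 0) {
          mask <- (matrix(stats::runif(length(R)), nrow(R), ncol(R)) >=
                     cfg$dropout) / (1 - cfg$dropout)
          H <- R * mask
        } else {
          mask <- NULL
          H <- R
        }
        mc$layers[[l]] <- list(Hin = Hin, bn = bnc, relu_in = bnc$out,
                               mask = mask)
      }
    }
    Z[[i]] <- H
    caches$modality[[i]] <- mc
  }
  Sf <- Z[[1]] %*% params$fuse_W1 + Z[[2]] %*% params$fuse_W2 +
    Z[[3]] %*% params$fuse_W3
  Sf <- sweep(Sf, 2L, params$fuse_b, "+")
  bnf <- bn_forward(Sf, params$fuse_gamma, params$fuse_beta,
                    bn_state[["fuse"]], train)
  if (train) {
    bn_state[["fuse"]]$mean <- momentum * bn_state[["fuse"]]$mean +
      (1 - momentum) * bnf$mu
    bn_state[["fuse"]]$var <- momentum * bn_state[["fuse"]]$var +
      (1 - momentum) * bnf$var
  }
  Rf <- relu(bnf$out)
  if (train && cfg$dropout > 0) {
    maskf <- (matrix(stats::runif(length(Rf)), nrow(Rf), ncol(Rf)) >=
                cfg$dropout) / (1 - cfg$dropout)
    Hf <- Rf * maskf
  } else {
    maskf <- NULL
    Hf <- Rf
  }
  logits <- sweep(Hf %*% params$out_W, 2L, params$out_b, "+")
  prob <- softmax_rows(logits)
  caches$Z <- Z
  caches$fuse <- list(bn = bnf, relu_in = bnf$out, mask = maskf, Hf = Hf)
  list(prob = prob, caches = caches, bn_state = bn_state)
}

# Gradients of mean BCE + L2 with respect to every parameter.
model_backward <- function(params, graphs, cfg, fw, y) {
  m <- length(y)
  lambda <- cfg$l2_lambda
  onehot <- cbind(1 - y, y)
  dlogits <- (fw$prob - onehot) / m
  grads <- list()
  cf <- fw$caches$fuse
  grads$out_W <- t(cf$Hf) %*% dlogits + 2 * lambda * params$out_W
  grads$out_b <- colSums(dlogits)
  dHf <- dlogits %*% t(params$out_W)
  if (!is.null(cf$mask)) dHf <- dHf * cf$mask
  dRf <- dHf * (cf$relu_in > 0)
  bnb <- bn_backward(dRf, cf$bn, params$fuse_gamma)
  grads$fuse_gamma <- bnb$dgamma
  grads$fuse_beta <- bnb$dbeta
  dSf <- bnb$dx
  grads$fuse_b <- colSums(dSf)
  Z <- fw$caches$Z
  dZ <- vector("list", 3L)
  for (i in 1:3) {
    Wf <- params[[sprintf("fuse_W%d", i)]]
    grads[[sprintf("fuse_W%d", i)]] <- t(Z[[i]]) %*% dSf + 2 * lambda * Wf
    dZ[[i]] <- dSf %*% t(Wf)
  }
  for (i in 1:3) {
    mc <- fw$caches$modality[[i]]
    dH <- dZ[[i]]
    if (cfg$depth > 0) {
      for (l in rev(seq_len(cfg$depth))) {
        key <- sprintf("m%d_l%d", i, l)
        lc <- mc$layers[[l]]
        if (!is.null(lc$mask)) dH <- dH * lc$mask
        dR <- dH * (lc$relu_in > 0)
        bnb <- bn_backward(dR, lc$bn, params[[paste0(key, "_gamma")]])
        grads[[paste0(key, "_gamma")]] <- bnb$dgamma
        grads[[paste0(key, "_beta")]] <- bnb$dbeta
        dS <- bnb$dx
        W <- params[[paste0(key, "_W")]]
        grads[[paste0(key, "_W")]] <- t(lc$Hin) %*% dS + 2 * lambda * W
        grads[[paste0(key, "_b")]] <- colSums(dS)
        dH <- dS %*% t(W)
      }
    }
    dS0 <- dH * (mc$S0 > 0)
    A <- graphs[[i]]$adjacency
    Win <- params[[sprintf("m%d_Win", i)]]
    grads[[sprintf("m%d_Win", i)]] <- (t(mc$X) %*% dS0) * A +
      2 * lambda * (Win * A)
    grads[[sprintf("m%d_bin", i)]] <- colSums(dS0)
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# L2 penalty on the effective weight matrices (masked input weights, dense,
# fusion and head weights; biases and batch-norm parameters excluded).
l2_penalty <- function(params, graphs, cfg) {
  s <- 0
  for (i in 1:3) {
    A <- graphs[[i]]$adjacency
    s <- s + sum((params[[sprintf("m%d_Win", i)]] * A)^2)
    if (cfg$depth > 0)
      for (l in seq_len(cfg$depth))
        s <- s + sum(params[[sprintf("m%d_l%d_W", i, l)]]^2)
    s <- s + sum(params[[sprintf("fuse_W%d", i)]]^2)
  }
  s + sum(params$out_W^2)
}

reduce_inputs <- function(x_list, graphs) {
  lapply(1:3, function(i) {
    v <- if (inherits(x_list[[i]], "omics_matrix")) x_list[[i]]$values
         else x_list[[i]]
    if (ncol(v) == length(graphs[[i]]$nodes)) v
    else v[, graphs[[i]]$col_map, drop = FALSE]
  })
}

#' Train the fused graph-embedded classifier
#'
#' Jointly optimizes three graph-embedded modality encoders and the fusion
#' classifier by mini-batch Adam on binary cross-entropy plus an L2 weight
#' penalty. The adjacency mask is re-applied at every forward pass, so
#' weight positions outside the graph can never influence predictions.
#' Training early-stops when the validation loss fails to improve by at
#' least `min_delta` for `patience` consecutive epochs, and the weights from
#' the best validation epoch are restored.
#'
#' @param train_x List of three [omics_matrix()] objects (normalized,
#'   full feature space) for the training split.
#' @param train_y Integer 0/1 labels for the training split.
#' @param graphs List of three [build_feature_graph()] results built from
#'   ensembles fitted on the same training split.
#' @param cfg A [training_config()].
#' @param val_x,val_y Validation split (same structure); both classes must
#'   be present in `val_y`.
#' @return An object of class `motgnn_model`: list with `params`,
#'   `bn_state`, `graphs`, `cfg`, `emb_widths` and `history` (data frame
#'   with epoch, train_loss, val_loss, lr).
#' @export
train_motgnn <- function(train_x, train_y, graphs, cfg = training_config(),
                         val_x, val_y) {
  train_y <- label_vector(train_y)
  if (length(unique(val_y)) < 2L)
    stop("empty validation stratum: both classes required in 'val_y'",
         call. = FALSE)
  set.seed(cfg$seed)
  init <- init_params(graphs, cfg)
  params <- init$params
  bn_state <- init$bn_state
  Xtr <- reduce_inputs(train_x, graphs)
  Xva <- reduce_inputs(val_x, graphs)
  n <- length(train_y)
  opt <- adam_init(params)
  best <- list(val = Inf, params = params, bn_state = bn_state)
  wait <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), lr = numeric(0))
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      Xb <- lapply(Xtr, function(m) m[idx, , drop = FALSE])
      fw <- model_forward(params, bn_state, graphs, cfg, Xb, train = TRUE)
      bn_state <- fw$bn_state
      grads <- model_backward(params, graphs, cfg, fw, train_y[idx])
      upd <- adam_step(params, grads, opt, cfg$learning_rate)
      params <- upd$params
      opt <- upd$state
    }
    tr_fw <- model_forward(params, bn_state, graphs, cfg, Xtr, train = FALSE)
    va_fw <- model_forward(params, bn_state, graphs, cfg, Xva, train = FALSE)
    tr_loss <- bce_loss(train_y, tr_fw$prob[, 2L])
    va_loss <- bce_loss(val_y, va_fw$prob[, 2L])
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = tr_loss,
                                val_loss = va_loss, lr = cfg$learning_rate))
    if (best$val - va_loss > cfg$min_delta) {
      best <- list(val = va_loss, params = params, bn_state = bn_state)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  structure(list(params = best$params, bn_state = best$bn_state,
                 graphs = graphs, cfg = cfg, emb_widths = init$emb_widths,
                 history = history),
            class = "motgnn_model")
}

#' @export
print.motgnn_model <- function(x, ...) {
  p_stars <- vapply(x$graphs, function(g) length(g$nodes), integer(1))
  cat(sprintf("<motgnn_model> p* = (%s), encoder depth %d x %d, fusion %d; trained %d epochs\n",
              paste(p_stars, collapse = ", "), x$cfg$depth, x$cfg$width,
              x$cfg$fusion_width, nrow(x$history)))
  invisible(x)
}

#' Predict class probabilities
#'
#' @param object A trained `motgnn_model`.
#' @param newdata List of three [omics_matrix()] objects (or matrices) in
#'   the full feature space of the training data; columns are reduced via
#'   each graph's `col_map`.
#' @param ... Unused.
#' @return Samples-by-2 matrix of class probabilities (columns `p0`, `p1`);
#'   rows sum to 1.
#' @export
predict.motgnn_model <- function(object, newdata, ...) {
  Xs <- reduce_inputs(newdata, object$graphs)
  ns <- vapply(Xs, nrow, integer(1))
  if (length(unique(ns)) != 1L)
    stop("sample-count mismatch across modalities", call. = FALSE)
  fw <- model_forward(object$params, object$bn_state, object$graphs,
                      object$cfg, Xs, train = FALSE)
  colnames(fw$prob) <- c("p0", "p1")
  fw$prob
}

#' Encode one modality into its embedding
#'
#' Runs the graph-embedded layer followed by the dense encoder stack of one
#' modality, producing the embedding `Z_i` that enters the fusion
#' classifier.
#'
#' @param model A trained `motgnn_model`.
#' @param modality Modality index 1..3.
#' @param X [omics_matrix()] or plain matrix; full feature space (reduced
#'   via `col_map`) or already reduced to `p*` columns.
#' @param train_mode If `TRUE`, use batch statistics and dropout (stochastic);
#'   default `FALSE` gives deterministic inference behavior.
#' @return Samples-by-embedding-width matrix `Z_i`.
#' @export
encode_modality <- function(model, modality, X, train_mode = FALSE) {
  stopifnot(inherits(model, "motgnn_model"), modality %in% 1:3)
  g <- model$graphs[[modality]]
  v <- if (inherits(X, "omics_matrix")) X$values else X
  if (ncol(v) != length(g$nodes)) {
    if (max(g$col_map) > ncol(v))
      stop("column-order mismatch: input is neither reduced nor full width",
           call. = FALSE)
    v <- v[, g$col_map, drop = FALSE]
  }
  cfg <- model$cfg
  params <- model$params
  H <- graph_embedded_forward(v, g$adjacency,
                              params[[sprintf("m%d_Win", modality)]],
                              params[[sprintf("m%d_bin", modality)]])
  if (cfg$depth > 0) {
    for (l in seq_len(cfg$depth)) {
      key <- sprintf("m%d_l%d", modality, l)
      S <- sweep(H %*% params[[paste0(key, "_W")]], 2L,
                 params[[paste0(key, "_b")]], "+")
      bnc <- bn_forward(S, params[[paste0(key, "_gamma")]],
                        params[[paste0(key, "_beta")]],
                        model$bn_state[[key]], train_mode)
      H <- relu(bnc$out)
      if (train_mode && cfg$dropout > 0)
        H <- H * ((matrix(stats::runif(length(H)), nrow(H), ncol(H)) >=
                     cfg$dropout) / (1 - cfg$dropout))
    }
  }
  H
}

#' Fuse modality embeddings and classify
#'
#' Concatenates the three embeddings (in modality order) through their
#' block fusion weights, applies the fusion hidden layer and the 2-unit
#' softmax head.
#'
#' @param model A `motgnn_model`.
#' @param Z1,Z2,Z3 Embedding matrices with equal row counts.
#' @param train_mode Stochastic training behavior if `TRUE`.
#' @return Samples-by-2 probability matrix; rows sum to 1.
#' @export
fuse_and_classify <- function(model, Z1, Z2, Z3, train_mode = FALSE) {
  ns <- c(nrow(Z1), nrow(Z2), nrow(Z3))
  if (length(unique(ns)) != 1L)
    stop("sample-count mismatch across embeddings", call. = FALSE)
  params <- model$params
  cfg <- model$cfg
  Sf <- Z1 %*% params$fuse_W1 + Z2 %*% params$fuse_W2 + Z3 %*% params$fuse_W3
  Sf <- sweep(Sf, 2L, params$fuse_b, "+")
  bnf <- bn_forward(Sf, params$fuse_gamma, params$fuse_beta,
                    model$bn_state[["fuse"]], train_mode)
  Hf <- relu(bnf$out)
  if (train_mode && cfg$dropout > 0)
    Hf <- Hf * ((matrix(stats::runif(length(Hf)), nrow(Hf), ncol(Hf)) >=
                   cfg$dropout) / (1 - cfg$dropout))
  logits <- sweep(Hf %*% params$out_W, 2L, params$out_b, "+")
  prob <- softmax_rows(logits)
  colnames(prob) <- c("p0", "p1")
  prob
}
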