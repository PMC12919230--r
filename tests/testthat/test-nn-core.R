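test_that("graph-embedded forward matches hand-computed products", {
  # diagonal mask: each output column is the input column times W[j,j]
  X <- matrix(c(1, 2, -1, 3), 2, 2)
  W <- matrix(c(2, 9, 9, 0.5), 2, 2)  # off-diagonals must be inert
  out <- graph_embedded_forward(X, diag(2), W, c(0, 0), activation = "identity")
  expect_equal(out, cbind(X[, 1] * 2, X[, 2] * 0.5))

  # hand matrix product with all-ones mask and ReLU
  X2 <- matrix(c(1, 2), 1, 2)
  W2 <- matrix(c(1, -1, 0.5, 1), 2, 2, byrow = TRUE)
  out2 <- graph_embedded_forward(X2, matrix(1, 2, 2), W2, c(0, 0))
  expect_equal(out2, matrix(c(2, 1), 1, 2))  # 1*1+2*0.5 = 2; max(0, -1+2) = 1

  expect_equal(graph_embedded_forward(matrix(0, 3, 2), matrix(1, 2, 2),
                                      W2, c(0, 0)),
               matrix(0, 3, 2))
  expect_error(graph_embedded_forward(X2, matrix(1, 3, 3), W2, c(0, 0)),
               "shape")
})

test_that("binary cross-entropy matches hand evaluations and clips safely", {
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(c(0, 1), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(c(0, 1, 1), c(0, 1, 1)), 1.2e-7 * 3)
  expect_true(is.finite(bce_loss(c(0, 1), c(1, 0))))
  expect_error(bce_loss(c(0, 1), 0.5), "length")
})

test_that("softmax head normalizes rows and reproduces hand probabilities", {
  p <- motgnn:::softmax_rows(matrix(c(0, log(3)), 1, 2))
  expect_equal(as.numeric(p), c(0.25, 0.75), tolerance = 1e-12)

  m <- random_tiny_model(2)
  X <- lapply(c(6, 5, 4), function(p) matrix(stats::rnorm(7 * p), 7, p))
  prob <- predict(m, X)
  expect_equal(unname(rowSums(prob)), rep(1, 7), tolerance = 1e-9)

  # zeroed fusion and head give symmetric logits: every sample (0.5, 0.5)
  z <- random_tiny_model(3)
  for (nm in c("fuse_W1", "fuse_W2", "fuse_W3", "out_W"))
    z$params[[nm]] <- z$params[[nm]] * 0
  z$params$fuse_b <- z$params$fuse_b * 0
  z$params$out_b <- z$params$out_b * 0
  Z <- lapply(z$emb_widths, function(w) matrix(stats::rnorm(4 * w), 4, w))
  p2 <- fuse_and_classify(z, Z[[1]], Z[[2]], Z[[3]])
  expect_equal(unname(p2), matrix(0.5, 4, 2), tolerance = 1e-12)

  # permuting samples permutes outputs identically
  perm <- c(3, 1, 4, 2)
  p3 <- fuse_and_classify(m, Z[[1]][perm, ], Z[[2]][perm, ], Z[[3]][perm, ])
  p3b <- fuse_and_classify(m, Z[[1]], Z[[2]], Z[[3]])[perm, ]
  expect_equal(p3, p3b, tolerance = 1e-12)
  expect_error(fuse_and_classify(m, Z[[1]][1:3, ], Z[[2]], Z[[3]]),
               "sample-count")
})

test_that("weights outside the adjacency mask never influence predictions", {
  m <- random_tiny_model(5)
  set.seed(101)
  X <- lapply(c(6, 5, 4), function(p) matrix(stats::runif(9 * p), 9, p))
  base <- predict(m, X)
  perturbed <- m
  for (i in 1:3) {
    nm <- sprintf("m%d_Win", i)
    A <- m$graphs[[i]]$adjacency
    noise <- matrix(stats::rnorm(length(A), sd = 10), nrow(A), ncol(A))
    perturbed$params[[nm]] <- m$params[[nm]] + noise * (A == 0)
  }
  expect_lte(max(abs(predict(perturbed, X) - base)), 1e-12)
})

test_that("zero-depth encoders pass the graph-embedded layer through unchanged", {
  m <- random_tiny_model(7, depth = 0L)
  X <- matrix(stats::runif(5 * 6), 5, 6)
  z <- encode_modality(m, 1, X)
  direct <- graph_embedded_forward(X, m$graphs[[1]]$adjacency,
                                   m$params$m1_Win, m$params$m1_bin)
  expect_equal(z, direct, tolerance = 1e-12)
  expect_identical(encode_modality(m, 1, X), encode_modality(m, 1, X))
})

test_that("analytic gradients agree with finite differences", {
  m <- random_tiny_model(13, p = c(3L, 3L, 2L), depth = 1L, width = 4L,
                         fusion_width = 4L)
  cfg <- m$cfg
  cfg$dropout <- 0          # deterministic forward for differencing
  cfg$l2_lambda <- 0.01
  set.seed(14)
  Xs <- lapply(c(3, 3, 2), function(p) matrix(stats::runif(6 * p), 6, p))
  y <- c(0L, 1L, 1L, 0L, 1L, 0L)
  params <- m$params
  loss_fn <- function(par) {
    fw <- motgnn:::model_forward(par, m$bn_state, m$graphs, cfg, Xs,
                                 train = TRUE)
    bce_loss(y, fw$prob[, 2]) +
      cfg$l2_lambda * motgnn:::l2_penalty(par, m$graphs, cfg)
  }
  fw <- motgnn:::model_forward(params, m$bn_state, m$graphs, cfg, Xs,
                               train = TRUE)
  grads <- motgnn:::model_backward(params, m$graphs, cfg, fw, y)
  eps <- 1e-6
  for (nm in names(grads)) {
    g <- grads[[nm]]
    idx <- seq_len(min(length(g), 6L))  # spot-check leading entries
    for (k in idx) {
      up <- params; up[[nm]][k] <- up[[nm]][k] + eps
      dn <- params; dn[[nm]][k] <- dn[[nm]][k] - eps
      num <- (loss_fn(up) - loss_fn(dn)) / (2 * eps)
      expect_equal(as.numeric(g[k]), num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, k))
    }
  }
})

test_that("L2 penalty strictly increases the objective for nonzero weights", {
  m <- random_tiny_model(9)
  pen <- motgnn:::l2_penalty(m$params, m$graphs, m$cfg)
  expect_gt(pen, 0)
  set.seed(4)
  Xs <- lapply(c(6, 5, 4), function(p) matrix(stats::runif(5 * p), 5, p))
  y <- c(1L, 0L, 1L, 0L, 1L)
  fw <- motgnn:::model_forward(m$params, m$bn_state, m$graphs, m$cfg, Xs)
  bce <- bce_loss(y, fw$prob[, 2])
  expect_gt(bce + 0.01 * pen, bce)
})

test_that("training separates strong synthetic signal and is seed-reproducible", {
  sim <- generate_multiomics(synthetic_config(
    n_samples = 100, dims = c(30, 30, 15),
    informative_per_modality = c(6, 6, 3), effect_size = 2, noise_sd = 0.3,
    seed = 19))
  run <- fit_pipeline(sim, seed = 3)
  prob_tr <- predict(run$fit, run$train)
  acc <- mean((prob_tr[, "p1"] >= 0.5) == run$y_train)
  expect_gte(acc, 0.95)

  run2 <- fit_pipeline(sim, seed = 3)
  expect_identical(run$fit$history, run2$fit$history)
  expect_identical(predict(run$fit, run$test), predict(run2$fit, run2$test))
})

test_that("early stopping halts at the first non-improving epoch when min_delta is huge", {
  m <- random_tiny_model(23)
  set.seed(6)
  Xtr <- lapply(c(6, 5, 4), function(p) {
    v <- matrix(stats::runif(20 * p), 20, p,
                dimnames = list(NULL, sprintf("x%d", seq_len(p))))
    v
  })
  y <- rep(c(0L, 1L), 10)
  cfg <- training_config(learning_rate = 1e-3, min_delta = 1e6, patience = 1L,
                         depth = 1L, width = 8L, fusion_width = 8L, seed = 2,
                         epochs = 50L)
  fit <- train_motgnn(Xtr, y, m$graphs, cfg, Xtr, y)
  expect_equal(nrow(fit$history), 2L)

  expect_error(train_motgnn(Xtr, y, m$graphs, cfg, Xtr, rep(1L, 20)),
               "validation stratum")
})
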