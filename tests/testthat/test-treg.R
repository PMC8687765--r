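test_that("distillation mimics the network, not the ground truth", {
  set.seed(1)
  X <- matrix(rnorm(400 * 12), 400, 12)
  # a constant network collapses to a single leaf with perfect fidelity
  tr0 <- distill_tree(rep("Q", 400), X)
  expect_true(tr0$is_leaf[1])
  expect_identical(attr(tr0, "fidelity"), 1)
  expect_identical(tree_predict(tr0, X[1:5, ]), rep("Q", 5))

  # a one-threshold decision function is recovered almost exactly
  preds <- ifelse(X[, 4] > 0.3, "N", "V")
  tr <- distill_tree(preds, X, min_samples_leaf = 5)
  expect_gte(attr(tr, "fidelity"), 0.99)

  # only the predictions enter the fit: rebuilding with the same predictions
  # yields the same tree regardless of any ground-truth labels
  tr2 <- distill_tree(preds, X, min_samples_leaf = 5)
  expect_identical(tidy(tr), tidy(tr2))
  expect_error(distill_tree(character(0), X[0, , drop = FALSE]), "sample")
})

test_that("average path length matches hand-enumerated trees", {
  # single leaf: no decisions
  leaf <- rhythmbeat:::new_sim_decision_tree(NA, NA, NA, NA, "N")
  expect_identical(average_path_length(leaf, matrix(rnorm(20), 10, 2)), 0)

  # complete depth-2 tree: every sample makes exactly 2 decisions
  full2 <- rhythmbeat:::new_sim_decision_tree(
    feature = c(1, 2, 2, NA, NA, NA, NA),
    threshold = c(0, 0, 0, NA, NA, NA, NA),
    left = c(2, 4, 6, NA, NA, NA, NA),
    right = c(3, 5, 7, NA, NA, NA, NA),
    leaf_class = c(NA, NA, NA, "N", "S", "V", "F")
  )
  X <- cbind(c(-1, -1, 1, 1), c(-1, 1, -1, 1))
  expect_identical(average_path_length(full2, X), 2)

  # root -> {leaf, internal -> {leaf, leaf}}: (2*1 + 2*2) / 4 = 1.5
  lop <- rhythmbeat:::new_sim_decision_tree(
    feature = c(1, NA, 1, NA, NA),
    threshold = c(0, NA, 0.5, NA, NA),
    left = c(2, NA, 4, NA, NA),
    right = c(3, NA, 5, NA, NA),
    leaf_class = c(NA, "N", NA, "S", "V")
  )
  Xl <- cbind(c(-1, -0.5, 0.2, 0.9), 0)
  expect_identical(average_path_length(lop, Xl), 1.5)
  expect_error(average_path_length(lop, Xl[0, , drop = FALSE]), "nonempty")
})

test_that("vectorized path lengths agree with independent per-sample walks", {
  set.seed(9)
  for (i in 1:100) {
    tr <- random_tree(d = 5, max_depth = 5)
    X <- matrix(runif(8 * 5, -1, 1), 8, 5)
    oracle <- mean(vapply(seq_len(nrow(X)),
                          function(r) walk_path_length(tr, X[r, ]), 0L))
    expect_identical(average_path_length(tr, X), oracle)
  }
})

test_that("the surrogate dataset enumerates checkpoints times perturbations", {
  set.seed(2)
  X <- matrix(rnorm(150 * 8), 150, 8)
  predict_fun <- function(w) ifelse(X[, 1] * w[1] + w[2] > 0, "N", "V")
  ckpts <- list(c(1, 0.1, rnorm(3)), c(0.5, -0.2, rnorm(3)),
                c(2, 0, rnorm(3)))
  ds <- build_surrogate_dataset(ckpts, X, predict_fun,
                                n_perturbations = 4, seed = 5,
                                min_samples_leaf = 5)
  expect_identical(nrow(ds), 15L) # 3 * (1 + 4)
  expect_true(all(ds$apl >= 0))
  ds2 <- build_surrogate_dataset(ckpts, X, predict_fun,
                                 n_perturbations = 4, seed = 5,
                                 min_samples_leaf = 5)
  expect_identical(ds$apl, ds2$apl)
  expect_error(build_surrogate_dataset(list(), X, predict_fun), "checkpoint")
})

test_that("the surrogate recovers a linear weight-to-APL map", {
  set.seed(7)
  d <- 20; J <- 200
  beta <- rnorm(d)
  Ws <- lapply(1:J, function(i) rnorm(d))
  apl <- vapply(Ws, function(w) 3 + sum(beta * w) / sqrt(d), 0)
  apl <- pmax(apl, 0)
  ds <- tibble::tibble(W = Ws, apl = apl)
  s <- train_surrogate(ds, epsilon = 0.1, epochs = 1500,
                       learning_rate = 0.02, input_jitter = 0, seed = 1)
  expect_lt(sqrt(s$holdout_mse), 0.05 * diff(range(apl)))
  # scalar, nonnegative output
  out <- surrogate_predict(s, Ws[[1]])
  expect_length(out, 1)
  expect_gte(out, 0)
})

test_that("extreme ridge strength collapses the surrogate toward a constant", {
  set.seed(8)
  d <- 10
  Ws <- lapply(1:50, function(i) rnorm(d))
  apl <- runif(50, 1, 6)
  ds <- tibble::tibble(W = Ws, apl = apl)
  s <- train_surrogate(ds, epsilon = 1e6, epochs = 300, seed = 2)
  preds <- surrogate_predict(s, do.call(rbind, Ws))
  expect_lt(stats::var(preds), 0.01 * stats::var(apl))
})

test_that("the joint objective is cross-entropy plus the surrogate penalty", {
  rec <- clean_record(12)
  segs <- assemble_segments(build_beats(rec), t = 3)
  batch <- segments_to_batch(segs)
  p <- init_bilstm_params(235, 3, seed = 1)
  ce <- base_loss(batch, p)
  # constant surrogate (zero hidden-to-output weights): penalty = softplus(b2)
  const_surr <- structure(
    list(W1 = matrix(0, 2, length(flatten_params(p))), b1 = c(0, 0),
         w2 = c(0, 0), b2 = 1.2, input_mean = flatten_params(p) * 0,
         input_scale = 1),
    class = "apl_surrogate"
  )
  cc <- log1p(exp(1.2))
  expect_equal(treg_loss(batch, p, const_surr, lambda = 1), ce + cc,
               tolerance = 1e-10)
  expect_equal(treg_loss(batch, p, const_surr, lambda = 0), ce,
               tolerance = 1e-12)
  expect_error(treg_loss(batch, p, NULL, 1), "not trained")
})

test_that("the surrogate penalty gradient matches finite differences", {
  set.seed(11)
  d <- 30
  Ws <- lapply(1:40, function(i) rnorm(d))
  apl <- vapply(Ws, function(w) 2 + abs(w[1]), 0)
  s <- train_surrogate(tibble::tibble(W = Ws, apl = apl), epochs = 200,
                       seed = 3)
  w0 <- rnorm(d)
  g <- surrogate_input_grad(s, w0)
  eps <- 1e-5
  num <- vapply(1:d, function(i) {
    wp <- w0; wp[i] <- wp[i] + eps
    wm <- w0; wm[i] <- wm[i] - eps
    (surrogate_predict(s, wp) - surrogate_predict(s, wm)) / (2 * eps)
  }, 0)
  expect_lt(max(abs(num - g)) / max(abs(num)), 1e-4)
})

test_that("tree-regularized training with lambda 0 equals plain training", {
  bench <- tiny_bench()
  segs <- bench$segments[1:20, ]
  cfg0 <- train_config(epochs = 3, batch_size = 8, hidden_size = 5,
                       timestep = 15, seed = 9, regularizer = "none")
  plain <- train_bilstm(segs, cfg0)
  cfgT <- train_config(epochs = 3, batch_size = 8, hidden_size = 5,
                       timestep = 15, seed = 9, regularizer = "tree",
                       lambda = 0)
  sch <- treg_schedule(distill_every = 1, n_perturbations = 1,
                       surrogate_epochs = 20, min_samples_leaf = 5)
  treg <- train_bilstm_treg(segs, cfgT, sch)
  expect_identical(flatten_params(plain$params),
                   flatten_params(treg$params))
  # one (APL, fidelity) record per distillation interval
  expect_identical(sum(!is.na(treg$history$apl_true)), 3L)
  expect_true(all(treg$history$fidelity >= 0 | is.na(treg$history$fidelity)))
  expect_s3_class(treg$tree, "sim_decision_tree")
})
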