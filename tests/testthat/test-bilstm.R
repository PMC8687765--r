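test_that("the LSTM cell equations reproduce hand-computed cases", {
  # all-zero parameters: every gate sits at sigmoid(0) = 0.5, candidate at
  # tanh(0) = 0, so the cell state and output are zero
  cell0 <- zero_cell(4, 3)
  st <- lstm_cell_step(rnorm(4), rnorm(3), numeric(3), cell0)
  expect_equal(st$i, rep(0.5, 3))
  expect_equal(st$f, rep(0.5, 3))
  expect_equal(st$o, rep(0.5, 3))
  expect_equal(st$g, rep(0, 3))
  expect_equal(st$c, rep(0, 3))
  expect_equal(st$h, rep(0, 3))

  # scalar case, all weights 1, biases 0, x = 0, h_prev = 0, c_prev = 1:
  # i = f = o = sigmoid(0) = 1/2, g = 0, C = 1/2 * 1 + 1/2 * 0 = 1/2,
  # h = 1/2 * tanh(1/2)
  cell1 <- lapply(zero_cell(1, 1), function(m) m + 1)
  cell1$b_i <- 0; cell1$b_f <- 0; cell1$b_o <- 0; cell1$b_c <- 0
  st1 <- lstm_cell_step(0, 0, 1, cell1)
  expect_equal(st1$c, 0.5, tolerance = 1e-12)
  expect_equal(st1$h, 0.5 * tanh(0.5), tolerance = 1e-12)

  expect_error(lstm_cell_step(rnorm(3), rnorm(3), numeric(3), cell0),
               "shape")
  expect_error(lstm_cell_step(c(1, NaN, 1, 1), rnorm(3), numeric(3), cell0),
               "non-finite")
})

test_that("hidden outputs are bounded by 1 in magnitude", {
  set.seed(2)
  for (i in 1:20) {
    cell <- lapply(zero_cell(5, 4), function(m) m + rnorm(length(m), 0, 2))
    st <- lstm_cell_step(rnorm(5), rnorm(4), rnorm(4, 0, 3), cell)
    expect_true(all(abs(st$h) <= 1))
  }
})

test_that("the bidirectional pass combines both directions as a weighted sum", {
  p <- init_bilstm_params(6, 4, seed = 3)
  for (t in c(1L, 5L, 15L)) {
    H <- bilstm_forward(matrix(rnorm(t * 6), t, 6), p)
    expect_identical(nrow(H), t)
    expect_identical(ncol(H), 4L)
  }
  # zero backward combination weights: the output is the pure forward LSTM
  pf <- p
  pf$w$comb$W_bwd <- pf$w$comb$W_bwd * 0
  pf$w$comb$b <- pf$w$comb$b * 0
  X <- matrix(rnorm(5 * 6), 5, 6)
  Hf <- bilstm_forward(X, pf)
  fwd_only <- rhythmbeat:::lstm_dir_forward(
    lapply(1:5, function(i) X[i, , drop = FALSE]), p$w$fwd, reverse = FALSE
  )
  expected <- do.call(rbind, lapply(fwd_only$hs,
                                    function(h) h %*% p$w$comb$W_fwd))
  expect_equal(Hf, expected, tolerance = 1e-12)
})

test_that("swapping directions and reversing the input reverses the output", {
  set.seed(6)
  for (rep in 1:5) {
    p <- init_bilstm_params(5, 3, seed = rep)
    ps <- p
    ps$w$fwd <- p$w$bwd; ps$w$bwd <- p$w$fwd
    ps$w$comb$W_fwd <- p$w$comb$W_bwd; ps$w$comb$W_bwd <- p$w$comb$W_fwd
    X <- matrix(rnorm(4 * 5), 4, 5)
    expect_equal(bilstm_forward(X, p),
                 bilstm_forward(X[4:1, ], ps)[4:1, ], tolerance = 1e-12)
  }
})

test_that("classification produces proper probability vectors", {
  p <- init_bilstm_params(8, 4, seed = 1)
  X <- matrix(rnorm(6 * 8), 6, 8)
  P <- classify_segment(X, p)
  expect_identical(dim(P), c(6L, 5L))
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))
  expect_identical(P, classify_segment(X, p))
  # zero head: uniform 0.2 everywhere
  p0 <- p
  p0$w$head$W <- p0$w$head$W * 0
  p0$w$head$b <- p0$w$head$b * 0
  expect_equal(unname(classify_segment(X, p0)), matrix(0.2, 6, 5),
               tolerance = 1e-12)
})

test_that("the base loss is cross-entropy plus the chosen weight penalty", {
  rec <- clean_record(16)
  segs <- assemble_segments(build_beats(rec), t = 4)
  batch <- segments_to_batch(segs)
  p <- init_bilstm_params(235, 4, seed = 2)
  # uniform predictions: per-beat cross-entropy is exactly log(5)
  p0 <- p
  p0$w$head$W <- p0$w$head$W * 0
  p0$w$head$b <- p0$w$head$b * 0
  expect_equal(base_loss(batch, p0), log(5), tolerance = 1e-12)
  # lambda = 0 reduces to pure cross-entropy; penalties add exactly
  ce <- base_loss(batch, p)
  expect_equal(base_loss(batch, p, "L2", lambda = 0), ce, tolerance = 1e-12)
  l2 <- sum(vapply(rhythmbeat:::weight_matrices(p),
                   function(m) sum(m^2), 0))
  expect_equal(base_loss(batch, p, "L2", lambda = 0.3), ce + 0.3 * l2,
               tolerance = 1e-10)
  l1 <- sum(vapply(rhythmbeat:::weight_matrices(p),
                   function(m) sum(abs(m)), 0))
  expect_equal(base_loss(batch, p, "L1", lambda = 2), ce + 2 * l1,
               tolerance = 1e-10)
})

test_that("analytic gradients match finite differences on a tiny network", {
  set.seed(3)
  D <- 6; H <- 3; t <- 2; B <- 3
  params <- init_bilstm_params(D, H, 5, seed = 11)
  X <- lapply(1:t, function(i) matrix(rnorm(B * D), B, D))
  Y <- matrix(sample(1:5, B * t, TRUE), B, t)
  mask <- matrix(TRUE, B, t)
  mask[1, 2] <- FALSE
  Y[1, 2] <- NA
  res <- rhythmbeat:::bilstm_loss_grad(X, Y, mask, params)
  gflat <- as.numeric(unlist(res$grads, use.names = FALSE))
  flat <- flatten_params(params)
  eps <- 1e-6
  num <- vapply(seq_along(flat), function(i) {
    fp <- flat; fp[i] <- fp[i] + eps
    fm <- flat; fm[i] <- fm[i] - eps
    (rhythmbeat:::bilstm_loss_grad(X, Y, mask,
                                   unflatten_params(fp, params),
                                   want_grads = FALSE)$ce -
       rhythmbeat:::bilstm_loss_grad(X, Y, mask,
                                     unflatten_params(fm, params),
                                     want_grads = FALSE)$ce) / (2 * eps)
  }, 0)
  expect_lt(max(abs(num - gflat)) / max(abs(num)), 1e-4)
})

test_that("training loss decreases on a trivially separable dataset", {
  # two rhythms whose classes are morphologically distinct (N vs V)
  recs <- list(clean_record(60, "normal_sinus", seed = 1),
               clean_record(60, "ventricular_tachycardia", seed = 2))
  beats <- dplyr::bind_rows(lapply(recs, build_beats))
  segs <- assemble_segments(beats, t = 5)
  cfg <- train_config(epochs = 5, batch_size = 8, hidden_size = 6,
                      timestep = 5, learning_rate = 5e-3, seed = 4)
  fit <- train_bilstm(segs, cfg)
  expect_identical(nrow(fit$history), 5L)
  expect_true(all(diff(fit$history$ce) < 0))
})

test_that("partial segments are padded and masked out of the loss", {
  rec <- clean_record(10)
  segs <- assemble_segments(build_beats(rec), t = 4) # 2 full + 1 of 2
  batch <- segments_to_batch(segs, t = 4)
  expect_identical(dim(batch$mask), c(3L, 4L))
  expect_identical(sum(batch$mask), 10L)
  expect_true(all(is.na(batch$Y[!batch$mask])))
  expect_true(all(batch$X[[4]][3, ] == 0)) # padded timestep is zeros
})
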