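# Bidirectional LSTM sequence classifier, implemented directly from the cell
# equations in base R matrix algebra:
#   i_t = sigmoid(W_i x_t + U_i h_{t-1} + b_i)
#   f_t = sigmoid(W_f x_t + U_f h_{t-1} + b_f)
#   o_t = sigmoid(W_o x_t + U_o h_{t-1} + b_o)
#   g_t = tanh   (W_c x_t + U_c h_{t-1} + b_c)      (candidate memory)
#   C_t = f_t * C_{t-1} + i_t * g_t
#   h_t = o_t * tanh(C_t)
# Two independent cells run over the segment left-to-right and right-to-left;
# their hidden states are combined by a weighted sum (not concatenation):
#   H_t = W_fwd h_fwd_t + W_bwd h_bwd_t + b_comb
# and a linear + softmax head maps each H_t to the five class probabilities.
# Batches are row-major: a batch of B segments at timestep t is a list of t
# input matrices [B x D].

sigmoid <- function(x) 1 / (1 + exp(-x))

add_bias <- function(M, b) sweep(M, 2, b, "+")

new_lstm_cell_params <- function(input_size, hidden_size, scale_in, scale_rec) {
  rw <- function(nr, nc, s) matrix(runif(nr * nc, -s, s), nr, nc)
  list(
    W_i = rw(input_size, hidden_size, scale_in),
    W_f = rw(input_size, hidden_size, scale_in),
    W_o = rw(input_size, hidden_size, scale_in),
    W_c = rw(input_size, hidden_size, scale_in),
    U_i = rw(hidden_size, hidden_size, scale_rec),
    U_f = rw(hidden_size, hidden_size, scale_rec),
    U_o = rw(hidden_size, hidden_size, scale_rec),
    U_c = rw(hidden_size, hidden_size, scale_rec),
    b_i = numeric(hidden_size),
    b_f = rep(1, hidden_size), # forget-gate bias 1: standard initialization
    b_o = numeric(hidden_size),
    b_c = numeric(hidden_size)
  )
}

#' Initialize BiLSTM parameters
#'
#' Uniform initialization scaled by `1/sqrt(fan-in)`; forget-gate biases start
#' at 1 so early training does not wash out the memory cell.
#'
#' @param input_size Per-timestep input dimension (235 for a full beat window
#'   at 360 Hz).
#' @param hidden_size Hidden state width of each directional cell.
#' @param n_classes Number of output classes (5).
#' @param seed Integer seed; `NULL` consumes the current RNG stream.
#' @return An object of class `bilstm_params`.
#' @export
init_bilstm_params <- function(input_size, hidden_size = 64, n_classes = 5,
                               seed = NULL) {
  make <- function() {
    s_in <- 1 / sqrt(input_size)
    s_rec <- 1 / sqrt(hidden_size)
    w <- list(
      fwd = new_lstm_cell_params(input_size, hidden_size, s_in, s_rec),
      bwd = new_lstm_cell_params(input_size, hidden_size, s_in, s_rec),
      comb = list(
        W_fwd = matrix(runif(hidden_size^2, -s_rec, s_rec), hidden_size),
        W_bwd = matrix(runif(hidden_size^2, -s_rec, s_rec), hidden_size),
        b = numeric(hidden_size)
      ),
      head = list(
        W = matrix(runif(hidden_size * n_classes, -s_rec, s_rec),
                   hidden_size, n_classes),
        b = numeric(n_classes)
      )
    )
    structure(
      list(input_size = as.integer(input_size),
           hidden_size = as.integer(hidden_size),
           n_classes = as.integer(n_classes), w = w),
      class = "bilstm_params"
    )
  }
  if (is.null(seed)) make() else with_local_seed(seed, make())
}

# Weight matrices only (no biases), for the L1/L2 penalty.
weight_matrices <- function(params) {
  w <- params$w
  c(
    w$fwd[c("W_i", "W_f", "W_o", "W_c", "U_i", "U_f", "U_o", "U_c")],
    w$bwd[c("W_i", "W_f", "W_o", "W_c", "U_i", "U_f", "U_o", "U_c")],
    list(w$comb$W_fwd, w$comb$W_bwd, w$head$W)
  )
}

#' Flatten BiLSTM parameters to a numeric vector
#'
#' The flattened vector is the network's parameter vector `W` as seen by the
#' tree-regularization surrogate. [unflatten_params()] inverts it.
#'
#' @param params A `bilstm_params` object.
#' @return Numeric vector.
#' @export
flatten_params <- function(params) as.numeric(unlist(params$w, use.names = FALSE))

#' @rdname flatten_params
#' @param flat Numeric vector from [flatten_params()].
#' @param template A `bilstm_params` object supplying shapes.
#' @export
unflatten_params <- function(flat, template) {
  template$w <- utils::relist(flat, skeleton = template$w)
  template
}

#' One LSTM cell step
#'
#' Evaluates the gate equations for a single timestep. Accepts a single input
#' vector (with vector states) or a batch given as rows of matrices.
#'
#' @param x_t Input: numeric vector of length D or matrix `[B x D]`.
#' @param h_prev,c_prev Previous hidden and memory state: vector of length H
#'   or matrix `[B x H]`.
#' @param cell A cell parameter list with `W_*` `[D x H]`, `U_*` `[H x H]`,
#'   `b_*` (length H) for gates `i`, `f`, `o` and candidate `c`.
#' @return List with `h` and `c` (same shape as `h_prev`), plus the gate
#'   activations `i`, `f`, `o`, `g`.
#' @export
lstm_cell_step <- function(x_t, h_prev, c_prev, cell) {
  vec_in <- is.null(dim(x_t))
  X <- if (vec_in) matrix(x_t, nrow = 1) else x_t
  Hp <- if (is.null(dim(h_prev))) matrix(h_prev, nrow = 1) else h_prev
  Cp <- if (is.null(dim(c_prev))) matrix(c_prev, nrow = 1) else c_prev
  if (any(!is.finite(X))) stop("non-finite inputs to lstm_cell_step")
  if (ncol(X) != nrow(cell$W_i) || ncol(Hp) != nrow(cell$U_i)) {
    stop("shape mismatch in lstm_cell_step")
  }
  i <- sigmoid(add_bias(X %*% cell$W_i + Hp %*% cell$U_i, cell$b_i))
  f <- sigmoid(add_bias(X %*% cell$W_f + Hp %*% cell$U_f, cell$b_f))
  o <- sigmoid(add_bias(X %*% cell$W_o + Hp %*% cell$U_o, cell$b_o))
  g <- tanh(add_bias(X %*% cell$W_c + Hp %*% cell$U_c, cell$b_c))
  cc <- f * Cp + i * g
  h <- o * tanh(cc)
  out <- list(h = h, c = cc, i = i, f = f, o = o, g = g)
  if (vec_in) out <- lapply(out, drop)
  out
}

# Run one directional cell over a segment batch.
# X: list of t matrices [B x D]; returns hidden states per timestep + cache.
lstm_dir_forward <- function(X, cell, reverse = FALSE, keep_cache = TRUE) {
  t_len <- length(X)
  B <- nrow(X[[1]])
  H <- length(cell$b_i)
  ord <- if (reverse) rev(seq_len(t_len)) else seq_len(t_len)
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  hs <- vector("list", t_len)
  cache <- if (keep_cache) vector("list", t_len) else NULL
  for (s in seq_len(t_len)) {
    tt <- ord[s]
    st <- lstm_cell_step(X[[tt]], h, cc, cell)
    if (keep_cache) {
      cache[[s]] <- list(tt = tt, h_prev = h, c_prev = cc,
                         i = st$i, f = st$f, o = st$o, g = st$g,
                         c = st$c, tanh_c = tanh(st$c))
    }
    h <- st$h
    cc <- st$c
    hs[[tt]] <- h
  }
  list(hs = hs, cache = cache, ord = ord)
}

# Backward pass of one direction. dh_out: list of t matrices [B x H], the
# gradient flowing into h_t from the combination layer.
lstm_dir_backward <- function(X, cell, fwd, dh_out) {
  t_len <- length(X)
  B <- nrow(X[[1]])
  H <- length(cell$b_i)
  g0 <- function(m) matrix(0, nrow(m), ncol(m))
  gr <- list(
    W_i = g0(cell$W_i), W_f = g0(cell$W_f), W_o = g0(cell$W_o), W_c = g0(cell$W_c),
    U_i = g0(cell$U_i), U_f = g0(cell$U_f), U_o = g0(cell$U_o), U_c = g0(cell$U_c),
    b_i = numeric(H), b_f = numeric(H), b_o = numeric(H), b_c = numeric(H)
  )
  dh_carry <- matrix(0, B, H)
  dc_carry <- matrix(0, B, H)
  for (s in rev(seq_len(t_len))) {
    cc <- fwd$cache[[s]]
    tt <- cc$tt
    dh <- dh_out[[tt]] + dh_carry
    do_ <- dh * cc$tanh_c
    dc <- dh * cc$o * (1 - cc$tanh_c^2) + dc_carry
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dpi <- di * cc$i * (1 - cc$i)
    dpf <- df * cc$f * (1 - cc$f)
    dpo <- do_ * cc$o * (1 - cc$o)
    dpg <- dg * (1 - cc$g^2)
    Xt <- t(X[[tt]])
    Hp <- t(cc$h_prev)
    gr$W_i <- gr$W_i + Xt %*% dpi
    gr$W_f <- gr$W_f + Xt %*% dpf
    gr$W_o <- gr$W_o + Xt %*% dpo
    gr$W_c <- gr$W_c + Xt %*% dpg
    gr$U_i <- gr$U_i + Hp %*% dpi
    gr$U_f <- gr$U_f + Hp %*% dpf
    gr$U_o <- gr$U_o + Hp %*% dpo
    gr$U_c <- gr$U_c + Hp %*% dpg
    gr$b_i <- gr$b_i + colSums(dpi)
    gr$b_f <- gr$b_f + colSums(dpf)
    gr$b_o <- gr$b_o + colSums(dpo)
    gr$b_c <- gr$b_c + colSums(dpg)
    dh_carry <- dpi %*% t(cell$U_i) + dpf %*% t(cell$U_f) +
      dpo %*% t(cell$U_o) + dpg %*% t(cell$U_c)
    dc_carry <- dc * cc$f
  }
  gr
}

# Full forward over a batch. Returns combined states, probabilities, caches.
bilstm_batch_forward <- function(X, params, keep_cache = TRUE) {
  w <- params$w
  fwd <- lstm_dir_forward(X, w$fwd, reverse = FALSE, keep_cache = keep_cache)
  bwd <- lstm_dir_forward(X, w$bwd, reverse = TRUE, keep_cache = keep_cache)
  t_len <- length(X)
  Hs <- vector("list", t_len)
  probs <- vector("list", t_len)
  for (tt in seq_len(t_len)) {
    Hc <- add_bias(fwd$hs[[tt]] %*% w$comb$W_fwd + bwd$hs[[tt]] %*% w$comb$W_bwd,
                   w$comb$b)
    Z <- add_bias(Hc %*% w$head$W, w$head$b)
    Z <- sweep(Z, 1, apply(Z, 1, max), "-")
    E <- exp(Z)
    Hs[[tt]] <- Hc
    probs[[tt]] <- E / rowSums(E)
  }
  list(fwd = fwd, bwd = bwd, Hs = Hs, probs = probs)
}

#' Bidirectional LSTM forward pass over one segment
#'
#' Runs the forward and backward cells over the beat sequence and combines
#' their hidden states by the weighted sum `H_t = W_fwd h_fwd_t +
#' W_bwd h_bwd_t + b`.
#'
#' @param segment_inputs Numeric matrix `[t x D]`, one row per beat.
#' @param params A `bilstm_params` object.
#' @return Matrix `[t x hidden_size]` of combined hidden states.
#' @export
bilstm_forward <- function(segment_inputs, params) {
  stopifnot(inherits(params, "bilstm_params"))
  X <- lapply(seq_len(nrow(segment_inputs)),
              function(tt) segment_inputs[tt, , drop = FALSE])
  out <- bilstm_batch_forward(X, params, keep_cache = FALSE)
  do.call(rbind, out$Hs)
}

#' Per-beat class probabilities for one segment
#'
#' Softmax head over the combined hidden states; the argmax of each row is
#' the beat's predicted AAMI class.
#'
#' @param segment A numeric matrix `[t x D]` or one row of an
#'   [assemble_segments()] tibble.
#' @param params A `bilstm_params` object.
#' @return Matrix `[t x 5]` of probabilities with columns `N,S,V,F,Q`; each
#'   row sums to 1.
#' @export
classify_segment <- function(segment, params) {
  if (is.data.frame(segment)) segment <- segment$samples[[1]]
  X <- lapply(seq_len(nrow(segment)),
              function(tt) segment[tt, , drop = FALSE])
  out <- bilstm_batch_forward(X, params, keep_cache = FALSE)
  P <- do.call(rbind, out$probs)
  colnames(P) <- aami_classes
  P
}

# Cross-entropy over the unmasked beats of a batch, plus gradients.
# Y: [B x t] integer class indices (NA where masked); mask: [B x t] logical.
bilstm_loss_grad <- function(X, Y, mask, params, want_grads = TRUE) {
  out <- bilstm_batch_forward(X, params, keep_cache = want_grads)
  w <- params$w
  t_len <- length(X)
  B <- nrow(X[[1]])
  H <- params$hidden_size
  M <- sum(mask)
  if (M == 0) stop("empty batch: no unmasked beats")
  ce <- 0
  dhf <- vector("list", t_len)
  dhb <- vector("list", t_len)
  gc_Wf <- matrix(0, H, H)
  gc_Wb <- matrix(0, H, H)
  gc_b <- numeric(H)
  gh_W <- matrix(0, H, params$n_classes)
  gh_b <- numeric(params$n_classes)
  for (tt in seq_len(t_len)) {
    P <- out$probs[[tt]]
    m <- mask[, tt]
    y <- Y[, tt]
    picked <- P[cbind(which(m), y[m])]
    ce <- ce - sum(log(pmax(picked, 1e-300)))
    if (want_grads) {
      dZ <- P
      dZ[cbind(which(m), y[m])] <- dZ[cbind(which(m), y[m])] - 1
      dZ[!m, ] <- 0
      dZ <- dZ / M
      gh_W <- gh_W + t(out$Hs[[tt]]) %*% dZ
      gh_b <- gh_b + colSums(dZ)
      dH <- dZ %*% t(w$head$W)
      gc_Wf <- gc_Wf + t(out$fwd$hs[[tt]]) %*% dH
      gc_Wb <- gc_Wb + t(out$bwd$hs[[tt]]) %*% dH
      gc_b <- gc_b + colSums(dH)
      dhf[[tt]] <- dH %*% t(w$comb$W_fwd)
      dhb[[tt]] <- dH %*% t(w$comb$W_bwd)
    }
  }
  ce <- ce / M
  res <- list(ce = ce, probs = out$probs)
  if (want_grads) {
    res$grads <- list(
      fwd = lstm_dir_backward(X, w$fwd, out$fwd, dhf),
      bwd = lstm_dir_backward(X, w$bwd, out$bwd, dhb),
      comb = list(W_fwd = gc_Wf, W_bwd = gc_Wb, b = gc_b),
      head = list(W = gh_W, b = gh_b)
    )
  }
  res
}

# L1/L2 penalty value and gradient over weight matrices (biases excluded).
weight_penalty <- function(params, regularizer) {
  mats <- weight_matrices(params)
  if (regularizer == "L1") {
    list(value = sum(vapply(mats, function(m) sum(abs(m)), 0)),
         grad_fun = function(m) sign(m))
  } else if (regularizer == "L2") {
    list(value = sum(vapply(mats, function(m) sum(m^2), 0)),
         grad_fun = function(m) 2 * m)
  } else {
    list(value = 0, grad_fun = function(m) 0 * m)
  }
}

apply_penalty_grads <- function(grads, params, lambda, grad_fun) {
  for (dir in c("fwd", "bwd")) {
    for (nm in c("W_i", "W_f", "W_o", "W_c", "U_i", "U_f", "U_o", "U_c")) {
      grads[[dir]][[nm]] <- grads[[dir]][[nm]] +
        lambda * grad_fun(params$w[[dir]][[nm]])
    }
  }
  grads$comb$W_fwd <- grads$comb$W_fwd + lambda * grad_fun(params$w$comb$W_fwd)
  grads$comb$W_bwd <- grads$comb$W_bwd + lambda * grad_fun(params$w$comb$W_bwd)
  grads$head$W <- grads$head$W + lambda * grad_fun(params$w$head$W)
  grads
}

#' Training objective of the base network
#'
#' Mean per-beat categorical cross-entropy over the unmasked beats of a batch
#' plus `lambda * Psi(W)`, where `Psi` is none, the L1 norm, or the squared L2
#' norm of the weight matrices. (The tree penalty is handled by
#' [treg_loss()].)
#'
#' @param batch A training batch from [segments_to_batch()].
#' @param params A `bilstm_params` object.
#' @param regularizer `"none"`, `"L1"` or `"L2"`.
#' @param lambda Penalty weight, `>= 0`.
#' @return Scalar loss.
#' @export
base_loss <- function(batch, params, regularizer = "none", lambda = 0) {
  res <- bilstm_loss_grad(batch$X, batch$Y, batch$mask, params,
                          want_grads = FALSE)
  pen <- weight_penalty(params, regularizer)
  res$ce + lambda * pen$value
}

#' Pack segment rows into a dense training batch
#'
#' Stacks the segments' beat matrices into per-timestep input matrices,
#' zero-padding partial segments up to `t` and recording a mask so padded
#' positions never contribute to the loss.
#'
#' @param segments Rows of an [assemble_segments()] tibble.
#' @param t Timestep to pad to; defaults to the longest segment present.
#' @param feature_indices Optional 1-based column subset of the beat window
#'   (for reduced-feature experiments).
#' @return List with `X` (list of `t` matrices `[B x D]`), `Y` (`[B x t]`
#'   class indices into `aami_classes`), `mask` (`[B x t]` logical), `t`, `D`.
#' @export
segments_to_batch <- function(segments, t = NULL, feature_indices = NULL) {
  B <- nrow(segments)
  if (B == 0) stop("empty batch")
  t <- as.integer(t %||% max(segments$t_actual))
  D_full <- ncol(segments$samples[[1]])
  keep <- feature_indices %||% seq_len(D_full)
  D <- length(keep)
  X <- lapply(seq_len(t), function(tt) matrix(0, B, D))
  Y <- matrix(NA_integer_, B, t)
  mask <- matrix(FALSE, B, t)
  for (b in seq_len(B)) {
    S <- segments$samples[[b]]
    ta <- segments$t_actual[b]
    for (tt in seq_len(min(ta, t))) {
      X[[tt]][b, ] <- S[tt, keep]
      Y[b, tt] <- match(segments$labels[[b]][tt], aami_classes)
      mask[b, tt] <- TRUE
    }
  }
  list(X = X, Y = Y, mask = mask, t = t, D = D)
}

# Per-beat predicted labels for a set of segments (unmasked beats only, in
# segment order). Returns character vector aligned with unlist(labels).
predict_beat_labels <- function(segments, params, feature_indices = NULL,
                                chunk_size = 256) {
  n <- nrow(segments)
  out <- vector("list", n)
  starts <- seq(1, n, by = chunk_size)
  for (s in starts) {
    rows <- s:min(s + chunk_size - 1, n)
    batch <- segments_to_batch(segments[rows, ], feature_indices = feature_indices)
    fw <- bilstm_batch_forward(batch$X, params, keep_cache = FALSE)
    for (k in seq_along(rows)) {
      ta <- segments$t_actual[rows[k]]
      out[[rows[k]]] <- vapply(seq_len(ta), function(tt) {
        aami_classes[which.max(fw$probs[[tt]][k, ])]
      }, "")
    }
  }
  unlist(out)
}
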