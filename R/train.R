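#' Training configuration
#'
#' Hyperparameters of the BiLSTM training run. None of these is dictated by
#' the model itself; the defaults are ordinary choices for a small sequence
#' classifier and every one is recorded in the returned fit.
#'
#' @param epochs Training epochs.
#' @param batch_size Segments per gradient step.
#' @param learning_rate Adam step size.
#' @param hidden_size Directional hidden width.
#' @param timestep Segment length `t` the data were assembled with.
#' @param regularizer `"none"`, `"L1"`, `"L2"` or `"tree"`.
#' @param lambda Penalty weight; defaults to 10 for `"tree"` (APL units) and
#'   1e-4 for L1/L2 (weight-norm units).
#' @param max_grad_norm Global gradient-norm clip applied before each Adam
#'   step (standard practice for recurrent nets; also bounds spikes from the
#'   surrogate penalty when its input scaling is ill-conditioned).
#' @param seed Integer seed governing initialization and batch shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 30, batch_size = 64, learning_rate = 1e-3,
                         hidden_size = 64, timestep = 15,
                         regularizer = c("none", "L1", "L2", "tree"),
                         lambda = NULL, max_grad_norm = 5, seed = 1) {
  regularizer <- match.arg(regularizer)
  lambda <- lambda %||% if (regularizer == "tree") 10 else 1e-4
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            hidden_size >= 1, timestep >= 1, lambda >= 0, max_grad_norm > 0)
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, hidden_size = as.integer(hidden_size),
         timestep = as.integer(timestep), regularizer = regularizer,
         lambda = lambda, max_grad_norm = max_grad_norm,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Tree-regularization schedule
#'
#' Controls the alternation between gradient steps on the joint objective and
#' the distill-and-refit-surrogate phase: every `distill_every` epochs the
#' network's predictions are refreshed, a tree is distilled, the surrogate
#' dataset is extended with the current parameters plus `n_perturbations`
#' Gaussian perturbations, and the surrogate is retrained. The penalty is
#' inactive until the first surrogate exists (warm-up).
#'
#' @param distill_every Epochs between distillations.
#' @param n_perturbations Parameter perturbations added per checkpoint.
#' @param surrogate_epochs Adam iterations when (re)training the surrogate.
#' @param epsilon Surrogate ridge strength.
#' @param max_depth,min_samples_leaf Tree constraints.
#' @param distill_sample Max number of beats used for distillation / APL
#'   measurement (subsampled deterministically when exceeded).
#' @return An object of class `treg_schedule`.
#' @export
treg_schedule <- function(distill_every = 2, n_perturbations = 4,
                          surrogate_epochs = 200, epsilon = 1e-3,
                          max_depth = 8, min_samples_leaf = 20,
                          distill_sample = 20000) {
  stopifnot(distill_every >= 1, n_perturbations >= 0, epsilon >= 0)
  structure(
    list(distill_every = as.integer(distill_every),
         n_perturbations = as.integer(n_perturbations),
         surrogate_epochs = as.integer(surrogate_epochs),
         epsilon = epsilon, max_depth = as.integer(max_depth),
         min_samples_leaf = as.integer(min_samples_leaf),
         distill_sample = as.integer(distill_sample)),
    class = "treg_schedule"
  )
}

adam_state <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_update <- function(flat, grad_flat, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad_flat
  state$v <- beta2 * state$v + (1 - beta2) * grad_flat^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(flat = flat - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# Flat matrix of all (unmasked) beats of a segment table, plus their labels —
# the distillation feature set x_n.
segments_to_beat_matrix <- function(segments, feature_indices = NULL) {
  mats <- segments$samples
  X <- do.call(rbind, mats)
  if (!is.null(feature_indices)) X <- X[, feature_indices, drop = FALSE]
  list(X = X, labels = unlist(segments$labels))
}

# Core training loop shared by plain and tree-regularized training. When
# `schedule` is NULL (or regularizer != "tree") no distillation happens and
# the run is bit-identical to plain training with the same config, because
# all treg-side randomness lives in its own RNG stream.
train_core <- function(segments, cfg, schedule = NULL,
                       feature_indices = NULL, surrogate_dataset = NULL,
                       quiet = TRUE) {
  stopifnot(inherits(cfg, "train_config"))
  use_tree <- cfg$regularizer == "tree"
  if (use_tree && is.null(schedule)) schedule <- treg_schedule()
  n_seg <- nrow(segments)
  bw_dim <- ncol(segments$samples[[1]])
  D <- length(feature_indices %||% seq_len(bw_dim))

  batch_full <- segments_to_batch(segments, t = cfg$timestep,
                                  feature_indices = feature_indices)
  n_beats <- sum(segments$t_actual)

  params <- init_bilstm_params(D, cfg$hidden_size, 5, seed = cfg$seed)
  flat <- flatten_params(params)
  ad <- adam_state(length(flat))
  surrogate <- NULL
  sdata <- surrogate_dataset
  tree <- NULL
  history <- list()
  pen <- weight_penalty(params, if (cfg$regularizer %in% c("L1", "L2"))
                                  cfg$regularizer else "none")

  # Distillation / APL measurement set: whole segments, subsampled when the
  # training set exceeds distill_sample beats.
  distill_segs <- if (!is.null(schedule) && n_beats > schedule$distill_sample) {
    with_local_seed(cfg$seed + 77003L, {
      ord_s <- sample.int(n_seg)
      sort(ord_s[cumsum(segments$t_actual[ord_s]) <= schedule$distill_sample])
    })
  } else seq_len(n_seg)
  segments_d <- if (!is.null(schedule)) segments[distill_segs, ] else NULL
  Xd <- if (!is.null(schedule)) {
    segments_to_beat_matrix(segments_d, feature_indices)$X
  } else NULL

  # Per-beat predictions in the beats' true segment context (the tree must
  # mimic what the network actually outputs, rhythm context included).
  predict_fun <- function(w_flat) {
    p <- unflatten_params(w_flat, params)
    predict_beat_labels(segments_d, p, feature_indices = feature_indices)
  }

  do_distill <- function(epoch) {
    preds <- predict_fun(flat)
    tr <- distill_tree(preds, Xd, max_depth = schedule$max_depth,
                       min_samples_leaf = schedule$min_samples_leaf)
    apl <- average_path_length(tr, Xd)
    new_pairs <- build_surrogate_dataset(
      checkpoints = list(flat), features = Xd, predict_fun = predict_fun,
      n_perturbations = schedule$n_perturbations,
      max_depth = schedule$max_depth,
      min_samples_leaf = schedule$min_samples_leaf,
      seed = cfg$seed + 13L * epoch
    )
    sdata <<- if (is.null(sdata)) new_pairs else
      dplyr::bind_rows(sdata, new_pairs)
    surrogate <<- train_surrogate(
      sdata, epsilon = schedule$epsilon,
      epochs = schedule$surrogate_epochs, seed = cfg$seed + 7L
    )
    tree <<- tr
    list(apl = apl, fidelity = attr(tr, "fidelity"))
  }

  set.seed(cfg$seed + 1L)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n_seg)
    ce_sum <- 0; n_batches <- 0
    for (s in seq(1, n_seg, by = cfg$batch_size)) {
      rows <- ord[s:min(s + cfg$batch_size - 1, n_seg)]
      bx <- lapply(batch_full$X, function(m) m[rows, , drop = FALSE])
      res <- bilstm_loss_grad(bx, batch_full$Y[rows, , drop = FALSE],
                              batch_full$mask[rows, , drop = FALSE], params)
      grads <- res$grads
      if (cfg$regularizer %in% c("L1", "L2")) {
        grads <- apply_penalty_grads(grads, params, cfg$lambda, pen$grad_fun)
      }
      gflat <- as.numeric(unlist(grads, use.names = FALSE))
      if (use_tree && !is.null(surrogate)) {
        gflat <- gflat + cfg$lambda * surrogate_input_grad(surrogate, flat)
      }
      gn <- sqrt(sum(gflat^2))
      mg <- cfg$max_grad_norm %||% 5
      if (gn > mg) gflat <- gflat * (mg / gn)
      up <- adam_update(flat, gflat, ad, cfg$learning_rate)
      flat <- up$flat
      ad <- up$state
      params <- unflatten_params(flat, params)
      ce_sum <- ce_sum + res$ce
      n_batches <- n_batches + 1
    }
    ep_entry <- list(
      epoch = epoch, ce = ce_sum / n_batches,
      penalty = if (use_tree && !is.null(surrogate)) {
        with_local_seed(NULL, surrogate_predict(surrogate, flat))
      } else if (cfg$regularizer %in% c("L1", "L2")) {
        weight_penalty(params, cfg$regularizer)$value
      } else NA_real_,
      apl_true = NA_real_, fidelity = NA_real_,
      surrogate_holdout_mse = NA_real_
    )
    if (use_tree && (epoch %% schedule$distill_every == 0 ||
                     epoch == cfg$epochs)) {
      dd <- with_local_seed(NULL, do_distill(epoch))
      ep_entry$apl_true <- dd$apl
      ep_entry$fidelity <- dd$fidelity
      ep_entry$surrogate_holdout_mse <- surrogate$holdout_mse
    }
    history[[epoch]] <- ep_entry
    if (!quiet) {
      message(sprintf("epoch %d/%d ce=%.4f", epoch, cfg$epochs, ep_entry$ce))
    }
  }

  structure(
    list(
      params = params, config = cfg, schedule = schedule,
      surrogate = surrogate, surrogate_dataset = sdata, tree = tree,
      feature_indices = feature_indices,
      history = dplyr::bind_rows(lapply(history, tibble::as_tibble)),
      n_segments = n_seg, n_beats = n_beats, input_size = D
    ),
    class = "bilstm_fit"
  )
}

#' Train a BiLSTM beat classifier
#'
#' Plain, L1- or L2-regularized training on assembled beat segments. For the
#' tree-regularized variant see [train_bilstm_treg()].
#'
#' @param segments Training rows of an [assemble_segments()] tibble.
#' @param cfg A [train_config()] with `regularizer` in
#'   `c("none", "L1", "L2")`.
#' @param quiet Suppress per-epoch messages.
#' @return A `bilstm_fit`: parameters, config, and an epoch-wise `history`
#'   tibble.
#' @export
train_bilstm <- function(segments, cfg = train_config(), quiet = TRUE) {
  if (cfg$regularizer == "tree") {
    stop("use train_bilstm_treg() for the tree regularizer")
  }
  train_core(segments, cfg, schedule = NULL, quiet = quiet)
}

#' Train a tree-regularized BiLSTM (BiLSTM-Treg)
#'
#' Alternates gradient steps on `cross-entropy + lambda * Omega_tilde(W)`
#' with periodic distillation: every `schedule$distill_every` epochs the
#' network's predictions are refreshed, a decision tree is distilled from
#' them, the (W, true-APL) surrogate dataset is extended (current parameters
#' plus Gaussian perturbations), and the surrogate MLP is retrained. Until
#' the first distillation the penalty is inactive (warm-up). With
#' `lambda = 0` the trajectory is identical to [train_bilstm()] under the
#' same config.
#'
#' @param segments Training rows of an [assemble_segments()] tibble.
#' @param cfg A [train_config()]; `regularizer` is forced to `"tree"`.
#' @param schedule A [treg_schedule()].
#' @param quiet Suppress per-epoch messages.
#' @return A `bilstm_fit` whose `tree` element is the final simulated
#'   decision tree and whose `history` logs true APL, fidelity and surrogate
#'   MSE at each distillation.
#' @export
train_bilstm_treg <- function(segments, cfg = train_config(regularizer = "tree"),
                              schedule = treg_schedule(), quiet = TRUE) {
  cfg$regularizer <- "tree"
  train_core(segments, cfg, schedule = schedule, quiet = quiet)
}

#' @export
print.bilstm_fit <- function(x, ...) {
  cat(sprintf(
    "<bilstm_fit: %d-d input, hidden %d, t=%d, %s%s, %d epochs on %d segments>\n",
    x$input_size, x$config$hidden_size, x$config$timestep,
    x$config$regularizer,
    if (x$config$regularizer != "none") sprintf(" (lambda=%g)", x$config$lambda)
    else "",
    x$config$epochs, x$n_segments
  ))
  invisible(x)
}

#' Per-beat predictions for segment rows
#'
#' @param object A `bilstm_fit`.
#' @param segments Rows of an [assemble_segments()] tibble.
#' @param ... Unused.
#' @return A tibble with one row per (unpadded) beat: `segment_id`,
#'   `position`, `truth`, `prediction`.
#' @export
predict.bilstm_fit <- function(object, segments, ...) {
  preds <- predict_beat_labels(segments, object$params,
                               feature_indices = object$feature_indices)
  tibble::tibble(
    segment_id = rep(segments$segment_id, segments$t_actual),
    position = unlist(lapply(segments$t_actual, seq_len)),
    truth = unlist(segments$labels),
    prediction = preds
  )
}

#' @export
tidy.bilstm_fit <- function(x, ...) x$history

#' @export
glance.bilstm_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    epochs = x$config$epochs,
    hidden_size = x$config$hidden_size,
    timestep = x$config$timestep,
    regularizer = x$config$regularizer,
    lambda = x$config$lambda,
    final_ce = last$ce,
    final_apl = last$apl_true,
    final_fidelity = last$fidelity,
    n_segments = x$n_segments,
    n_beats = x$n_beats
  )
}
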