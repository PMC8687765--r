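# Differentiable surrogate for the average path length. The true APL of the
# tree distilled from a network with parameter vector W is a step function of
# W (not differentiable), so a small MLP is regressed on pairs
# {(W_j, APL_j)}: one hidden tanh layer, softplus output to keep the
# predicted APL nonnegative, ridge penalty epsilon * ||xi||^2 on its weights.
# Its gradient with respect to W is what flows back into the network.

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Train the APL surrogate regressor
#'
#' Minimizes `sum_j (APL_j - Omega_tilde(W_j))^2 + epsilon * ||xi||^2` over
#' the surrogate's weights `xi` by full-batch Adam. Inputs are standardized
#' internally (per-dimension mean; a single global scale) so the ridge term
#' acts on comparable weights.
#'
#' @param dataset A tibble from [build_surrogate_dataset()] (columns `W`
#'   list-column, `apl`), or a list with those elements.
#' @param epsilon Ridge strength (default 1e-3).
#' @param hidden_units Hidden layer width (default 25).
#' @param epochs Adam iterations (default 400).
#' @param learning_rate Adam step size.
#' @param input_jitter Gaussian jitter (in standardized input units) added to
#'   the training inputs, refreshed every few iterations. The true APL is a
#'   step function of the parameters, so an exact fit would be flat almost
#'   everywhere; jitter trains the regressor on a locally smoothed version,
#'   which is what makes its gradient usable as a penalty. 0 disables.
#' @param holdout_frac Fraction of pairs held out to report generalization
#'   MSE; 0 disables.
#' @param seed Integer seed for initialization and the holdout draw.
#' @return An object of class `apl_surrogate` with elements `W1`, `b1`, `w2`,
#'   `b2`, input normalization, and `train_mse` / `holdout_mse`.
#' @export
train_surrogate <- function(dataset, epsilon = 1e-3, hidden_units = 25,
                            epochs = 400, learning_rate = 0.01,
                            input_jitter = 0.3, holdout_frac = 0.2, seed = 1) {
  Ws <- dataset$W
  apl <- dataset$apl
  J <- length(apl)
  if (J < 2) stop("need at least 2 (W, APL) pairs")
  X <- do.call(rbind, Ws) # [J x d]
  d <- ncol(X)
  with_local_seed(seed, {
    hold <- if (holdout_frac > 0 && J >= 5) {
      sample.int(J, max(1, round(holdout_frac * J)))
    } else integer(0)
    tr <- setdiff(seq_len(J), hold)
    mu <- colMeans(X[tr, , drop = FALSE])
    # scale so the typical checkpoint-to-checkpoint *distance* is O(1): the
    # smoothing jitter and the tanh nonlinearity then act at a useful scale
    # instead of saturating (per-entry standardization would put the data
    # ~sqrt(d) apart)
    sc <- sd(sweep(X[tr, , drop = FALSE], 2, mu)) * sqrt(d)
    if (!is.finite(sc) || sc == 0) sc <- 1
    Xn <- sweep(X, 2, mu) / sc
    h <- hidden_units
    p <- list(
      W1 = matrix(rnorm(h * d, 0, 1), h, d),
      b1 = numeric(h),
      w2 = rnorm(h, 0, 1 / sqrt(h)),
      b2 = log(expm1(max(mean(apl[tr]), 1e-6))) # softplus^-1 of the mean APL
    )
    if (!is.finite(p$b2)) p$b2 <- 0
    Xtr <- Xn[tr, , drop = FALSE]
    atr <- apl[tr]
    # per-tensor Adam; full-batch gradients (J is tiny, d is large)
    m <- lapply(p, function(x) x * 0)
    v <- lapply(p, function(x) x * 0)
    Xuse <- Xtr
    for (it in seq_len(epochs)) {
      if (input_jitter > 0 && it %% 10 == 1) {
        # per-entry sd input_jitter/sqrt(d) => displacement norm ~input_jitter
        Xuse <- Xtr + matrix(rnorm(length(Xtr), 0, input_jitter / sqrt(d)),
                             nrow(Xtr), ncol(Xtr))
      }
      A <- tanh(sweep(Xuse %*% t(p$W1), 2, p$b1, "+")) # [n x h]
      pre <- drop(A %*% p$w2) + p$b2
      dout <- 2 * (softplus(pre) - atr) * sigmoid(pre)
      dA <- outer(dout, p$w2) * (1 - A^2)
      g <- list(
        W1 = crossprod(dA, Xuse) + 2 * epsilon * p$W1,
        b1 = colSums(dA),
        w2 = drop(crossprod(A, dout)) + 2 * epsilon * p$w2,
        b2 = sum(dout)
      )
      c1 <- 1 - 0.9^it
      c2 <- 1 - 0.999^it
      for (nm in names(p)) {
        m[[nm]] <- 0.9 * m[[nm]] + 0.1 * g[[nm]]
        v[[nm]] <- 0.999 * v[[nm]] + 0.001 * g[[nm]]^2
        p[[nm]] <- p[[nm]] - learning_rate * (m[[nm]] / c1) /
          (sqrt(v[[nm]] / c2) + 1e-8)
      }
    }
    pred_rows <- function(rows) {
      A <- tanh(sweep(Xn[rows, , drop = FALSE] %*% t(p$W1), 2, p$b1, "+"))
      softplus(drop(A %*% p$w2) + p$b2)
    }
    structure(
      list(
        W1 = p$W1, b1 = p$b1, w2 = p$w2, b2 = p$b2,
        input_mean = mu, input_scale = sc, epsilon = epsilon,
        train_mse = mean((pred_rows(tr) - apl[tr])^2),
        holdout_mse = if (length(hold)) mean((pred_rows(hold) - apl[hold])^2)
                      else NA_real_,
        n_train = length(tr), n_holdout = length(hold)
      ),
      class = "apl_surrogate"
    )
  })
}

#' Predicted APL for a parameter vector
#'
#' @param surrogate An `apl_surrogate`.
#' @param w_flat Numeric parameter vector (as from [flatten_params()]), or a
#'   matrix of such vectors as rows.
#' @return Nonnegative scalar (or vector for matrix input).
#' @export
surrogate_predict <- function(surrogate, w_flat) {
  X <- if (is.null(dim(w_flat))) matrix(w_flat, nrow = 1) else w_flat
  Xn <- sweep(X, 2, surrogate$input_mean) / surrogate$input_scale
  A <- tanh(sweep(Xn %*% t(surrogate$W1), 2, surrogate$b1, "+"))
  out <- softplus(drop(A %*% surrogate$w2) + surrogate$b2)
  if (is.null(dim(w_flat))) out[1] else out
}

#' Gradient of the surrogate APL with respect to the parameter vector
#'
#' @inheritParams surrogate_predict
#' @return Numeric vector of the same length as `w_flat`.
#' @export
surrogate_input_grad <- function(surrogate, w_flat) {
  xn <- (w_flat - surrogate$input_mean) / surrogate$input_scale
  z <- drop(surrogate$W1 %*% xn) + surrogate$b1
  a <- tanh(z)
  pre <- sum(a * surrogate$w2) + surrogate$b2
  dpre <- sigmoid(pre)
  drop(crossprod(surrogate$W1, dpre * surrogate$w2 * (1 - a^2))) /
    surrogate$input_scale
}

#' Collect (parameter vector, true APL) pairs for the surrogate
#'
#' For each checkpointed parameter vector and each of `n_perturbations`
#' Gaussian perturbations of it, the network is instantiated, its per-beat
#' predictions computed, a tree distilled, and the true APL measured —
#' yielding `J = |checkpoints| * (1 + n_perturbations)` training pairs.
#'
#' @param checkpoints List of flat parameter vectors.
#' @param features Numeric matrix `[n x D]` of beat windows used both for
#'   prediction and for the APL measurement.
#' @param predict_fun Function mapping a flat parameter vector to a character
#'   vector of per-beat predictions on `features`.
#' @param n_perturbations Perturbations per checkpoint.
#' @param noise_sd Perturbation scale; default `0.1 * sd(W)` per checkpoint.
#' @param max_depth,min_samples_leaf Tree constraints for [distill_tree()].
#' @param seed Integer seed for the perturbations.
#' @return A tibble with list-column `W` and column `apl`.
#' @export
build_surrogate_dataset <- function(checkpoints, features, predict_fun,
                                    n_perturbations = 4, noise_sd = NULL,
                                    max_depth = 8, min_samples_leaf = 20,
                                    seed = 1) {
  if (length(checkpoints) < 1) stop("need at least 1 checkpoint")
  with_local_seed(seed, {
    pairs_W <- list()
    pairs_apl <- numeric(0)
    for (ck in checkpoints) {
      sd_k <- noise_sd %||% (0.1 * sd(ck))
      variants <- c(list(ck), lapply(seq_len(n_perturbations), function(i) {
        ck + rnorm(length(ck), 0, sd_k)
      }))
      for (w in variants) {
        preds <- predict_fun(w)
        tree <- distill_tree(preds, features, max_depth = max_depth,
                             min_samples_leaf = min_samples_leaf)
        pairs_W <- c(pairs_W, list(w))
        pairs_apl <- c(pairs_apl, average_path_length(tree, features))
      }
    }
    tibble::tibble(W = pairs_W, apl = pairs_apl)
  })
}

#' Tree-regularized training objective
#'
#' The joint objective: mean per-beat cross-entropy plus
#' `lambda * Omega_tilde(W)`, the surrogate-predicted average path length of
#' the simulated decision tree. Differentiable in the network parameters
#' through the surrogate.
#'
#' @param batch A batch from [segments_to_batch()].
#' @param params A `bilstm_params` object.
#' @param surrogate A trained `apl_surrogate`.
#' @param lambda Penalty weight, `>= 0`.
#' @return Scalar loss.
#' @export
treg_loss <- function(batch, params, surrogate, lambda) {
  if (!inherits(surrogate, "apl_surrogate")) stop("surrogate is not trained")
  res <- bilstm_loss_grad(batch$X, batch$Y, batch$mask, params,
                          want_grads = FALSE)
  res$ce + lambda * surrogate_predict(surrogate, flatten_params(params))
}
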