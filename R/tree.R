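# Simulated decision tree (SDT): the axis-aligned binary tree distilled from
# the network's predictions. Stored as parallel node vectors so routing whole
# matrices through it is vectorizable. Node ids are 1-based; `left`/`right`
# are child ids (NA at leaves). `tally` holds the per-node count of routed
# training samples per AAMI class.

new_sim_decision_tree <- function(feature, threshold, left, right,
                                  leaf_class, tally = NULL) {
  n <- length(feature)
  stopifnot(length(threshold) == n, length(left) == n, length(right) == n,
            length(leaf_class) == n)
  is_leaf <- is.na(left)
  if (any(!is_leaf & (is.na(feature) | !is.finite(threshold)))) {
    stop("internal nodes need a feature index and finite threshold")
  }
  structure(
    list(
      feature = as.integer(feature), threshold = as.numeric(threshold),
      left = as.integer(left), right = as.integer(right),
      leaf_class = as.character(leaf_class), is_leaf = is_leaf,
      tally = tally
    ),
    class = "sim_decision_tree"
  )
}

#' @export
print.sim_decision_tree <- function(x, ...) {
  cat(sprintf("<sim_decision_tree: %d nodes (%d leaves), depth %d>\n",
              length(x$feature), sum(x$is_leaf), tree_depth(x)))
  invisible(x)
}

tree_depth <- function(tree) {
  depth <- function(id, d) {
    if (tree$is_leaf[id]) return(d)
    max(depth(tree$left[id], d + 1L), depth(tree$right[id], d + 1L))
  }
  depth(1L, 0L)
}

# Route rows of X; returns a list with the leaf id and the number of internal
# decision nodes traversed (== path length) per row.
tree_route <- function(tree, X) {
  n <- nrow(X)
  node <- rep(1L, n)
  steps <- integer(n)
  active <- !tree$is_leaf[node]
  while (any(active)) {
    ids <- which(active)
    cur <- node[ids]
    goes_left <- X[cbind(ids, tree$feature[cur])] < tree$threshold[cur]
    node[ids] <- ifelse(goes_left, tree$left[cur], tree$right[cur])
    steps[ids] <- steps[ids] + 1L
    active[ids] <- !tree$is_leaf[node[ids]]
  }
  list(leaf = node, path_length = steps)
}

#' Predict classes with a simulated decision tree
#'
#' @param tree A `sim_decision_tree`.
#' @param X Numeric matrix, one sample per row, columns = beat-window sample
#'   points.
#' @return Character vector of AAMI class predictions.
#' @export
tree_predict <- function(tree, X) {
  tree$leaf_class[tree_route(tree, X)$leaf]
}

#' Average path length of a tree over a sample set
#'
#' The mean, over the rows of `X`, of the number of internal decision nodes
#' traversed from the root to the sample's leaf. This is the tree-complexity
#' penalty of tree regularization: a single-leaf tree scores 0, a complete
#' depth-d tree scores d for every sample.
#'
#' @param tree A `sim_decision_tree`.
#' @param X Numeric matrix of samples (rows).
#' @return Nonnegative scalar.
#' @export
average_path_length <- function(tree, X) {
  if (is.null(dim(X)) || nrow(X) == 0) stop("X must be a nonempty matrix")
  mean(tree_route(tree, X)$path_length)
}

# Convert a fitted rpart classification tree into a sim_decision_tree.
# rpart frames index nodes by binary-heap numbers; primary splits sit in
# blocks of rpart$splits rows, one block per internal node in frame order.
rpart_to_sdt <- function(fit, class_levels) {
  frame <- fit$frame
  node_num <- as.integer(rownames(frame))
  n <- nrow(frame)
  id_of <- match(node_num, node_num)
  lookup <- function(num) match(num, node_num)
  feature <- rep(NA_integer_, n)
  threshold <- rep(NA_real_, n)
  left <- rep(NA_integer_, n)
  right <- rep(NA_integer_, n)
  leaf_class <- rep(NA_character_, n)
  ylevels <- attr(fit, "ylevels")
  tally <- frame$yval2[, 1 + seq_along(ylevels), drop = FALSE]
  colnames(tally) <- ylevels
  split_row <- 1L
  splits <- fit$splits
  for (k in seq_len(n)) {
    if (frame$var[k] == "<leaf>") {
      leaf_class[k] <- ylevels[frame$yval[k]]
      next
    }
    nsub <- frame$ncompete[k] + frame$nsurrogate[k] + 1L
    sp <- splits[split_row, , drop = TRUE]
    split_row <- split_row + nsub
    feat_name <- rownames(splits)[split_row - nsub]
    feature[k] <- as.integer(sub("^f", "", feat_name))
    threshold[k] <- sp[["index"]]
    l <- lookup(node_num[k] * 2L)
    r <- lookup(node_num[k] * 2L + 1L)
    # ncat = -1: x < threshold goes left; +1: x >= threshold goes left
    if (sp[["ncat"]] < 0) {
      left[k] <- l; right[k] <- r
    } else {
      left[k] <- r; right[k] <- l
    }
  }
  # reorder tallies to canonical AAMI order, filling absent classes with 0
  full_tally <- matrix(0L, n, length(class_levels),
                       dimnames = list(NULL, class_levels))
  full_tally[, colnames(tally)] <- tally
  new_sim_decision_tree(feature, threshold, left, right, leaf_class,
                        tally = full_tally)
}

#' Distill a decision tree that mimics the network
#'
#' Fits a CART tree on `(x_n, yhat_n)` where `yhat_n` are the *network's*
#' per-beat predictions (never the ground truth): the tree learns to simulate
#' the network's decision function, and the fraction of samples on which it
#' succeeds is its fidelity.
#'
#' @param predictions Character vector of network-predicted AAMI labels, one
#'   per beat.
#' @param features Numeric matrix `[n x 235]` of raw beat windows (rows
#'   aligned with `predictions`).
#' @param max_depth Maximum tree depth (default 8).
#' @param min_samples_leaf Minimum samples per leaf (default 20). Both
#'   constraints keep the APL stable and the tree human-simulable.
#' @return A `sim_decision_tree` with attributes `fidelity` (in `[0,1]`) and
#'   `n_train`.
#' @export
distill_tree <- function(predictions, features, max_depth = 8,
                         min_samples_leaf = 20) {
  n <- length(predictions)
  if (n < 1 || is.null(dim(features)) || nrow(features) != n) {
    stop("need >= 1 sample with features aligned to predictions")
  }
  present <- sort(unique(predictions))
  if (length(present) == 1) {
    # constant network: a single leaf reproduces it exactly
    tree <- new_sim_decision_tree(NA, NA, NA, NA, present,
                                  tally = {
                                    tl <- matrix(0L, 1, 5,
                                                 dimnames = list(NULL, aami_classes))
                                    tl[1, present] <- n
                                    tl
                                  })
    attr(tree, "fidelity") <- 1
    attr(tree, "n_train") <- n
    return(tree)
  }
  df <- as.data.frame(features)
  names(df) <- paste0("f", seq_len(ncol(features)))
  df$.y <- factor(predictions, levels = aami_classes[aami_classes %in% present])
  fit <- rpart::rpart(
    .y ~ ., data = df, method = "class",
    control = rpart::rpart.control(
      maxdepth = max_depth, minbucket = min_samples_leaf,
      minsplit = max(2L * min_samples_leaf, 2L),
      cp = 1e-4, xval = 0, maxcompete = 0, maxsurrogate = 0,
      usesurrogate = 0
    )
  )
  tree <- rpart_to_sdt(fit, aami_classes)
  attr(tree, "fidelity") <- mean(tree_predict(tree, features) == predictions)
  attr(tree, "n_train") <- n
  tree
}

#' Tidy a simulated decision tree into a node table
#'
#' @param x A `sim_decision_tree`.
#' @param ... Unused.
#' @return A tibble with one row per node: `node_id`, `is_leaf`, `feature`
#'   (0-based beat-window sample index), `threshold`, `left`, `right`,
#'   `leaf_class`, and per-class training tallies.
#' @export
tidy.sim_decision_tree <- function(x, ...) {
  out <- tibble::tibble(
    node_id = seq_along(x$feature),
    is_leaf = x$is_leaf,
    feature = x$feature - 1L, # report 0-based window positions
    threshold = x$threshold,
    left = x$left, right = x$right,
    leaf_class = x$leaf_class
  )
  if (!is.null(x$tally)) {
    tl <- tibble::as_tibble(as.data.frame(x$tally))
    names(tl) <- paste0("n_", names(tl))
    out <- dplyr::bind_cols(out, tl)
  }
  out
}

#' Serialize a simulated decision tree to JSON
#'
#' @param tree A `sim_decision_tree`.
#' @param path Output file path.
#' @export
write_sdt_json <- function(tree, path) {
  jsonlite::write_json(
    list(
      feature = tree$feature - 1L, threshold = tree$threshold,
      left = tree$left, right = tree$right, leaf_class = tree$leaf_class,
      tally = tree$tally
    ),
    path, auto_unbox = FALSE, digits = NA, na = "null"
  )
  invisible(path)
}

#' Export a simulated decision tree to Graphviz DOT
#'
#' Internal nodes are labelled with their split (`x[f] < thr`); leaves with
#' their class. Node value annotations (per-class percentages) can be merged
#' in from [node_value_percentages()].
#'
#' @param tree A `sim_decision_tree`.
#' @param path Output file path.
#' @param values Optional tibble from [node_value_percentages()].
#' @export
write_sdt_dot <- function(tree, path, values = NULL) {
  n <- length(tree$feature)
  lab <- character(n)
  for (k in seq_len(n)) {
    lab[k] <- if (tree$is_leaf[k]) {
      sprintf("leaf: %s", tree$leaf_class[k])
    } else {
      sprintf("x[%d] < %.4f", tree$feature[k] - 1L, tree$threshold[k])
    }
    if (!is.null(values)) {
      v <- values[values$node_id == k, grepl("^pct_", names(values))]
      if (nrow(v) == 1) {
        lab[k] <- paste0(lab[k], "\\n",
                         paste(sprintf("%s=%.2f", sub("pct_", "", names(v)),
                                       as.numeric(v[1, ])), collapse = " "))
      }
    }
  }
  lines <- c("digraph sdt {", "  node [shape=box];",
             sprintf('  n%d [label="%s"];', seq_len(n), lab))
  for (k in which(!tree$is_leaf)) {
    lines <- c(lines,
               sprintf("  n%d -> n%d [label=\"yes\"];", k, tree$left[k]),
               sprintf("  n%d -> n%d [label=\"no\"];", k, tree$right[k]))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
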