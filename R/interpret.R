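# Simulated-decision-tree analyses: which beat-window sample points the
# distilled tree splits on, and how the beat classes flow through its nodes.

tree_node_depths <- function(tree) {
  n <- length(tree$feature)
  depth <- integer(n)
  walk <- function(id, d) {
    depth[id] <<- d
    if (!tree$is_leaf[id]) {
      walk(tree$left[id], d + 1L)
      walk(tree$right[id], d + 1L)
    }
  }
  walk(1L, 0L)
  depth
}

#' Per-node class percentages of a simulated decision tree
#'
#' Routes every sample through the tree and reports, at each node, the
#' percentage of each class's *total* beats that pass through that node (so
#' the root shows 100 for every class present, and sibling subtrees partition
#' the parent's percentage). A value like `pct_S = 0.08` at a node means the
#' node holds 0.08% of all class-S beats — i.e. the split above it separated
#' S almost completely.
#'
#' @param tree A `sim_decision_tree`.
#' @param X Numeric matrix of beat windows (rows aligned with `labels`).
#' @param labels True (or network-predicted) AAMI labels per row of `X`.
#' @return A tibble with one row per node: `node_id`, `depth`, `is_leaf`,
#'   `feature` (0-based), `threshold`, `leaf_class`, `n_samples`, and
#'   `pct_N` .. `pct_Q` (NA for a class absent from `labels`).
#' @export
node_value_percentages <- function(tree, X, labels) {
  if (nrow(X) != length(labels)) stop("labels must align with rows of X")
  n_nodes <- length(tree$feature)
  # tally per node including pass-through at internal nodes
  node_tally <- matrix(0L, n_nodes, 5, dimnames = list(NULL, aami_classes))
  cls_idx <- match(labels, aami_classes)
  node <- rep(1L, nrow(X))
  done <- rep(FALSE, nrow(X))
  repeat {
    for (cl in 1:5) {
      sel <- cls_idx == cl & !done
      if (any(sel)) {
        tb <- tabulate(node[sel], nbins = n_nodes)
        node_tally[, cl] <- node_tally[, cl] + tb
      }
    }
    at_leaf <- tree$is_leaf[node]
    done <- done | at_leaf
    if (all(done)) break
    ids <- which(!at_leaf)
    cur <- node[ids]
    goes_left <- X[cbind(ids, tree$feature[cur])] < tree$threshold[cur]
    node[ids] <- ifelse(goes_left, tree$left[cur], tree$right[cur])
  }
  totals <- colSums(node_tally[tree$is_leaf, , drop = FALSE])
  pct <- sweep(node_tally, 2, totals, function(a, b) ifelse(b == 0, NA, 100 * a / b))
  out <- tibble::tibble(
    node_id = seq_len(n_nodes),
    depth = tree_node_depths(tree),
    is_leaf = tree$is_leaf,
    feature = tree$feature - 1L,
    threshold = tree$threshold,
    leaf_class = tree$leaf_class,
    n_samples = as.integer(rowSums(node_tally))
  )
  pct_df <- tibble::as_tibble(as.data.frame(pct))
  names(pct_df) <- paste0("pct_", aami_classes)
  dplyr::bind_cols(out, pct_df)
}

# Gini impurity of a tally row.
gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts / n
  1 - sum(p^2)
}

#' Rank beat-window feature points by tree importance
#'
#' Feature importance is the total Gini impurity decrease contributed by all
#' splits on a feature (weighted by the number of samples reaching the
#' split), normalized to sum to 1 over used features. Ties break toward the
#' lower feature index. `method = "split_count"` ranks by the number of
#' splits instead.
#'
#' @param tree A `sim_decision_tree` with node tallies (from
#'   [distill_tree()]).
#' @param k Number of top features to return.
#' @param method `"gini"` (default) or `"split_count"`.
#' @return A tibble with columns `feature` (0-based beat-window index) and
#'   `importance`, sorted descending, at most `k` rows. Importances are
#'   normalized before truncation.
#' @export
rank_features <- function(tree, k = 10, method = c("gini", "split_count")) {
  method <- match.arg(method)
  if (k < 1) stop("k must be >= 1")
  internal <- which(!tree$is_leaf)
  if (length(internal) == 0) {
    return(tibble::tibble(feature = integer(0), importance = numeric(0)))
  }
  imp <- numeric(0)
  for (id in internal) {
    w <- if (method == "gini") {
      tl <- tree$tally
      parent <- tl[id, ]
      lft <- tl[tree$left[id], ]
      rgt <- tl[tree$right[id], ]
      n <- sum(parent)
      n * gini_impurity(parent) - sum(lft) * gini_impurity(lft) -
        sum(rgt) * gini_impurity(rgt)
    } else 1
    key <- as.character(tree$feature[id])
    imp[key] <- (if (key %in% names(imp)) imp[key] else 0) + w
  }
  total <- sum(imp)
  if (total > 0) imp <- imp / total
  feats <- as.integer(names(imp))
  ord <- order(-imp, feats)
  out <- tibble::tibble(feature = feats[ord] - 1L, importance = unname(imp[ord]))
  head(out, k)
}

#' Retrain on a reduced set of beat-window feature points
#'
#' Projects every beat onto the given sample points (e.g. the top-10
#' important features of the simulated decision tree), retrains the
#' tree-regularized classifier on the projected training segments, and
#' evaluates on the projected test segments — the check that the selected
#' points really carry the class signal.
#'
#' @param train_segments,test_segments Rows of an [assemble_segments()]
#'   tibble.
#' @param feature_indices 0-based beat-window sample indices to keep.
#' @param cfg A [train_config()].
#' @param schedule A [treg_schedule()] (used when `cfg$regularizer` is
#'   `"tree"`).
#' @return A list with the reduced-input `fit` and its `evaluation`.
#' @export
reduced_feature_experiment <- function(train_segments, test_segments,
                                       feature_indices,
                                       cfg = train_config(regularizer = "tree"),
                                       schedule = treg_schedule()) {
  D <- ncol(train_segments$samples[[1]])
  if (length(feature_indices) == 0 ||
      any(feature_indices < 0 | feature_indices >= D)) {
    stop("feature_indices must be 0-based indices into the beat window")
  }
  idx1 <- sort(unique(as.integer(feature_indices))) + 1L
  fit <- train_core(train_segments, cfg,
                    schedule = if (cfg$regularizer == "tree") schedule else NULL,
                    feature_indices = idx1)
  list(fit = fit, evaluation = evaluate_fit(fit, test_segments))
}

#' Bar chart of top feature-point importances
#'
#' @param object A tibble from [rank_features()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_feature_ranking <- function(object, ...) {
  df <- dplyr::mutate(object,
                      feature = factor(.data$feature,
                                       levels = rev(.data$feature)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Normalized importance (Gini decrease)",
                  y = "Beat-window sample point (0-based)")
}
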