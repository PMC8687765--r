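# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# A small mixed-rhythm benchmark (all five classes present).
tiny_bench <- function() {
  if (is.null(fixture_env$bench)) {
    fixture_env$bench <- benchmark_dataset(
      n_beats = 900, t = 15, seed = 101, beats_per_record = 50
    )
  }
  fixture_env$bench
}

# A clean (noise-free, jitter-free) record for arithmetic checks.
clean_record <- function(n_beats = 20, rhythm = "normal_sinus",
                         heart_rate_bpm = 60, seed = 5) {
  generate_record(
    rhythm_spec(rhythm, n_beats, heart_rate_bpm = heart_rate_bpm,
                rate_jitter_frac = 0),
    noise_spec(baseline_wander_amp = 0, powerline_amp = 0, gaussian_sd = 0),
    fs = 360, seed = seed
  )
}

# Random axis-aligned binary tree over d features, for APL oracle tests.
# Grown top-down; each node becomes a leaf with prob p_leaf or at max depth.
random_tree <- function(d = 6, max_depth = 5, p_leaf = 0.35) {
  feature <- integer(0); threshold <- numeric(0)
  left <- integer(0); right <- integer(0); leaf_class <- character(0)
  grow <- function(depth) {
    id <- length(feature) + 1L
    feature[id] <<- NA_integer_; threshold[id] <<- NA_real_
    left[id] <<- NA_integer_; right[id] <<- NA_integer_
    leaf_class[id] <<- NA_character_
    if (depth >= max_depth || runif(1) < p_leaf) {
      leaf_class[id] <<- sample(aami_classes, 1)
      return(id)
    }
    feature[id] <<- sample.int(d, 1)
    threshold[id] <<- runif(1, -1, 1)
    left[id] <<- grow(depth + 1L)
    right[id] <<- grow(depth + 1L)
    id
  }
  grow(0L)
  rhythmbeat:::new_sim_decision_tree(feature, threshold, left, right,
                                     leaf_class)
}

# Independent per-sample recursive walk: the APL oracle.
walk_path_length <- function(tree, x) {
  id <- 1L; steps <- 0L
  while (!tree$is_leaf[id]) {
    id <- if (x[tree$feature[id]] < tree$threshold[id]) tree$left[id]
          else tree$right[id]
    steps <- steps + 1L
  }
  steps
}

# Hand-built zero cell (all weights/biases zero) of given sizes.
zero_cell <- function(D, H) {
  z <- function(nr, nc) matrix(0, nr, nc)
  list(W_i = z(D, H), W_f = z(D, H), W_o = z(D, H), W_c = z(D, H),
       U_i = z(H, H), U_f = z(H, H), U_o = z(H, H), U_c = z(H, H),
       b_i = numeric(H), b_f = numeric(H), b_o = numeric(H),
       b_c = numeric(H))
}
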