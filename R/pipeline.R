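# The standard synthetic benchmark and the experiment sweeps (segment-length
# grid, regularizer comparison). The benchmark mixes rhythm grammars so that
# all five AAMI classes occur and part of the class signal is contextual
# (premature beats arrive early; fusion beats follow ventricular runs), which
# is exactly what segment-level classification is supposed to exploit.

benchmark_grammars <- function() {
  list(
    list(name = "ventricular_bigeminy"),
    list(name = "atrial_bigeminy"),
    list(name = "ventricular_trigeminy"),
    list(name = "atrial_trigeminy"),
    list(name = "ventricular_tachycardia"),
    list(name = "atrial_tachycardia"),
    list(name = "normal_sinus"),
    # ventricular run ending in a fusion beat then sinus capture
    list(name = "custom", pattern = c("V", "V", "V", "F", "N", "N")),
    # continuously paced rhythm
    list(name = "custom", pattern = c("Q", "Q", "Q", "Q"))
  )
}

#' Generate the standard synthetic arrhythmia benchmark
#'
#' A collection of records cycling through the rhythm grammars (bigeminy,
#' trigeminy, ventricular/atrial tachycardia, normal sinus, a
#' ventricular-run-with-fusion pattern, and a paced pattern) under the
#' default noise model, denoised, cut into beats, and assembled into
#' segments. This fixes the study conditions every training experiment runs
#' under.
#'
#' @param n_beats Total number of beats across all records (default 10000).
#' @param t Segment length (default 15).
#' @param fs Sampling rate (default 360).
#' @param seed Generator seed.
#' @param beats_per_record Beats per simulated record.
#' @param noise A [noise_spec()].
#' @param denoise_cfg A [wavelet_config()], or `NULL` to skip denoising.
#' @param heart_rate_bpm Base heart rate.
#' @param rate_jitter_frac Inter-beat interval jitter fraction.
#' @return A list: `segments` (tibble), `beats` (tibble), `records` (list of
#'   `ecg_record`), and the generation arguments.
#' @export
benchmark_dataset <- function(n_beats = 10000, t = 15, fs = 360, seed = 42,
                              beats_per_record = 250,
                              noise = noise_spec(),
                              denoise_cfg = wavelet_config(),
                              heart_rate_bpm = 75, rate_jitter_frac = 0.05) {
  grammars <- benchmark_grammars()
  records <- list()
  beats_left <- n_beats
  k <- 0
  while (beats_left > 0) {
    g <- grammars[[(k %% length(grammars)) + 1]]
    nb <- min(beats_per_record, beats_left)
    spec <- rhythm_spec(
      g$name, n_beats = nb, heart_rate_bpm = heart_rate_bpm,
      rate_jitter_frac = rate_jitter_frac,
      custom_pattern = g$pattern %||% NULL
    )
    rec <- generate_record(spec, noise = noise, fs = fs, seed = seed + k,
                           record_id = sprintf("bench-%03d-%s", k,
                                               g$name))
    if (!is.null(denoise_cfg)) rec <- denoise_record(rec, denoise_cfg)
    records[[length(records) + 1]] <- rec
    beats_left <- beats_left - nb
    k <- k + 1
  }
  beats <- dplyr::bind_rows(lapply(records, build_beats))
  segments <- assemble_segments(beats, t = t)
  list(segments = segments, beats = beats, records = records,
       n_beats = n_beats, t = t, fs = fs, seed = seed)
}

#' Run the segment-length / regularizer experiment grid
#'
#' Trains and evaluates one model per grid cell (timestep x regularizer x
#' seed), reassembling segments at each timestep from the same beat table so
#' every cell sees the same beats.
#'
#' @param beats A beat tibble from [build_beats()] (e.g.
#'   `benchmark_dataset(...)$beats`).
#' @param t_grid Segment lengths to sweep (the canonical sweep is
#'   `c(1, 5, 10, 15, 20, 25, 30)`).
#' @param regularizer_grid Subset of `c("none", "L1", "L2", "tree")`.
#' @param cfg Base [train_config()]; `timestep` and `regularizer` are
#'   overridden per cell.
#' @param schedule A [treg_schedule()] for tree cells.
#' @param lambdas Named penalty weights per regularizer.
#' @param seeds Training seeds; one row is produced per (cell, seed).
#' @param train_fraction,split_seed Segment-level train/test split control.
#' @param csv_path Optional path to also write the results as CSV.
#' @return A tibble with one row per run: `timestep`, `regularizer`, `seed`,
#'   `overall_accuracy`, `final_apl`, `final_fidelity`, and per-class
#'   sensitivity columns.
#' @export
run_experiment_grid <- function(beats, t_grid = c(1, 15),
                                regularizer_grid = c("none", "tree"),
                                cfg = train_config(),
                                schedule = treg_schedule(),
                                lambdas = c(none = 0, L1 = 1e-4, L2 = 1e-4,
                                            tree = 10),
                                seeds = cfg$seed,
                                train_fraction = 0.9, split_seed = 1,
                                csv_path = NULL) {
  stopifnot(length(t_grid) >= 1, length(regularizer_grid) >= 1)
  rows <- list()
  for (t in t_grid) {
    segments <- assemble_segments(beats, t = t)
    parts <- split_dataset(segments, train_fraction, seed = split_seed)
    for (reg in regularizer_grid) {
      for (sd_ in seeds) {
        cell_cfg <- cfg
        cell_cfg$timestep <- as.integer(t)
        cell_cfg$regularizer <- reg
        cell_cfg$seed <- as.integer(sd_)
        cell_cfg$lambda <- unname(lambdas[reg])
        fit <- if (reg == "tree") {
          train_bilstm_treg(parts$train, cell_cfg, schedule)
        } else {
          train_bilstm(parts$train, cell_cfg)
        }
        ev <- evaluate_fit(fit, parts$test)
        gl <- glance(fit)
        se <- stats::setNames(ev$metrics$Se, paste0("Se_", ev$metrics$class))
        rows[[length(rows) + 1]] <- tibble::tibble(
          timestep = t, regularizer = reg, seed = sd_,
          overall_accuracy = ev$overall_accuracy,
          final_apl = gl$final_apl, final_fidelity = gl$final_fidelity,
          !!!as.list(se)
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(csv_path)) write.csv(out, csv_path, row.names = FALSE)
  out
}

#' Plot a stretch of an ECG record
#'
#' Waveform with R-peak markers colored by AAMI class.
#'
#' @param object An `ecg_record`.
#' @param from,to Sample range to show (0-based; defaults to the first 2000
#'   samples).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecg_record <- function(object, from = 0,
                                to = min(2000, length(object$signal) - 1),
                                ...) {
  df <- tibble::tibble(sample = from:to,
                       mV = object$signal[(from:to) + 1])
  pk <- tibble::tibble(sample = object$r_peaks, label = object$beat_labels)
  pk <- pk[pk$sample >= from & pk$sample <= to, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(data = pk,
                        ggplot2::aes(y = object$signal[.data$sample + 1],
                                     color = .data$label)) +
    ggplot2::labs(x = "Sample", y = "mV", color = "AAMI class")
}
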