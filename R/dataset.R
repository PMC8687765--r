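# Annotation bookkeeping: MIT-BIH beat annotation symbols grouped into the
# five ANSI/AAMI EC57 classes. Any symbol not listed (rhythm-change '+',
# artifacts, non-beat markers) is excluded from beat building.
AAMI_SYMBOL_MAP <- list(
  N = c("N", "L", "R", "j", "e"),
  S = c("a", "J", "A", "S"),
  V = c("V", "E"),
  F = c("F"),
  Q = c("/", "Q", "f")
)

# Representative MIT-BIH symbol emitted by the synthetic generator per class.
aami_to_symbol <- function(labels) {
  unname(c(N = "N", S = "A", V = "V", F = "F", Q = "/")[labels])
}

#' Map annotation symbols to AAMI heartbeat classes
#'
#' Groups the MIT-BIH beat annotation codes into the five AAMI classes:
#' N gets `{N, L, R, j, e}`, S gets `{a, J, A, S}`, V gets `{V, E}`, F gets
#' `{F}`, Q gets `{/, Q, f}`. Every other symbol (rhythm markers, artifacts)
#' maps to `NA`, meaning "excluded": it is not a beat and is dropped by
#' [build_beats()].
#'
#' @param symbols Character vector of single-character annotation codes.
#' @return Character vector of the same length with values in
#'   `aami_classes` or `NA` for excluded symbols.
#' @export
#' @examples
#' map_annotation_to_aami(c("L", "A", "/", "+"))
map_annotation_to_aami <- function(symbols) {
  out <- rep(NA_character_, length(symbols))
  for (cls in names(AAMI_SYMBOL_MAP)) {
    out[symbols %in% AAMI_SYMBOL_MAP[[cls]]] <- cls
  }
  out
}

#' Extract one fixed-length beat window around an R peak
#'
#' Returns the samples from `round(0.25 fs)` before to `round(0.4 fs)` after
#' the R-peak sample, inclusive — 235 samples at 360 Hz, with the peak at
#' 0-based window index 90.
#'
#' @param signal Numeric vector (mV).
#' @param r_index 0-based sample index of the R peak.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of length `beat_window(fs)$length`.
#' @export
segment_beat <- function(signal, r_index, fs = 360) {
  bw <- beat_window(fs)
  lo <- r_index - bw$before
  hi <- r_index + bw$after
  if (lo < 0 || hi >= length(signal)) {
    stop("beat window out of record bounds (boundary beat)")
  }
  signal[(lo + 1L):(hi + 1L)]
}

#' Build the beat table of a record
#'
#' One row per annotated peak whose symbol maps to an AAMI class and whose
#' window fits inside the record; beats with excluded symbols or
#' boundary-crossing windows are dropped (counts reported in the
#' `n_dropped_boundary` / `n_dropped_symbol` attributes), never padded.
#'
#' @param record An `ecg_record` with `r_peaks` and either `symbols` or
#'   `beat_labels`.
#' @return A tibble with columns `source_record`, `position_in_record`
#'   (0-based among kept beats' original positions), `r_index`, `symbol`,
#'   `label`, `r_index_in_window` and list-column `samples`.
#' @export
build_beats <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  if (length(record$r_peaks) == 0) stop("record has no annotations")
  bw <- beat_window(record$fs)
  symbols <- record$symbols %||% aami_to_symbol(record$beat_labels)
  labels <- map_annotation_to_aami(symbols)
  keep_sym <- !is.na(labels)
  in_bounds <- record$r_peaks - bw$before >= 0 &
    record$r_peaks + bw$after < length(record$signal)
  keep <- keep_sym & in_bounds
  idx <- which(keep)
  samples <- lapply(record$r_peaks[idx], function(r) {
    segment_beat(record$signal, r, record$fs)
  })
  out <- tibble::tibble(
    source_record = record$record_id,
    position_in_record = idx - 1L,
    r_index = record$r_peaks[idx],
    symbol = symbols[idx],
    label = labels[idx],
    r_index_in_window = bw$r_index,
    samples = samples
  )
  attr(out, "n_dropped_boundary") <- sum(keep_sym & !in_bounds)
  attr(out, "n_dropped_symbol") <- sum(!keep_sym)
  out
}

#' Group consecutive beats into rhythm-preserving segments
#'
#' Within each source record, beats are chunked in order into non-overlapping
#' runs of `t` (the network timestep). A final partial run of length `< t` is
#' kept and flagged `partial`; at batch time it is zero-padded and the padded
#' positions are masked out of the loss. Every beat lands in exactly one
#' segment.
#'
#' @param beats A beat tibble from [build_beats()] (rows from several records
#'   may be concatenated with [dplyr::bind_rows()]).
#' @param t Segment length (timestep), `>= 1`.
#' @return A tibble with one row per segment: `segment_id`, `source_record`,
#'   `t_actual`, `partial`, list-columns `labels` (length-`t_actual`
#'   character) and `samples` (`t_actual x window` numeric matrix).
#' @export
#' @examples
#' rec <- generate_record(rhythm_spec("normal_sinus", 30), seed = 2)
#' segs <- assemble_segments(build_beats(rec), t = 15)
#' nrow(segs)
assemble_segments <- function(beats, t) {
  if (t < 1) stop("t must be >= 1")
  t <- as.integer(t)
  pieces <- split(beats, factor(beats$source_record,
                                levels = unique(beats$source_record)))
  segs <- purrr::map(pieces, function(b) {
    n <- nrow(b)
    chunk <- (seq_len(n) - 1L) %/% t
    purrr::map(split(seq_len(n), chunk), function(rows) {
      list(
        source_record = b$source_record[rows[1]],
        t_actual = length(rows),
        partial = length(rows) < t,
        labels = b$label[rows],
        samples = do.call(rbind, b$samples[rows])
      )
    })
  })
  flat <- unname(purrr::flatten(segs))
  tibble::tibble(
    segment_id = seq_along(flat) - 1L,
    source_record = purrr::map_chr(flat, "source_record"),
    t_actual = purrr::map_int(flat, "t_actual"),
    partial = purrr::map_lgl(flat, "partial"),
    labels = purrr::map(flat, "labels"),
    samples = purrr::map(flat, "samples")
  )
}

#' Random train/test split
#'
#' Seed-deterministic disjoint partition of the rows of a segment (or beat)
#' tibble, with `round(train_fraction * n)` rows in the training part. The
#' split unit is the row, so splitting the segment table keeps segments
#' intact; pass a beat table instead for a beat-level split.
#'
#' @param data A tibble (segments from [assemble_segments()] by default).
#' @param train_fraction Fraction in (0, 1); default 0.9.
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test`.
#' @export
split_dataset <- function(data, train_fraction = 0.9, seed = 1) {
  n <- nrow(data)
  if (n < 2) stop("need at least 2 rows to split")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie in (0, 1)")
  }
  n_train <- round(train_fraction * n)
  if (n_train < 1 || n_train >= n) stop("degenerate split sizes")
  idx <- with_local_seed(seed, sample.int(n, n_train))
  list(train = data[sort(idx), ], test = data[-sort(idx), ])
}
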