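# Record I/O. Two routes:
#  * plain text: a CSV of (sample, mV) plus a JSON sidecar with fs, r_peaks,
#    labels and symbols — the fixture-friendly format;
#  * a minimal WFDB subset: format-16 .dat (16-bit little-endian, gain 200
#    adu/mV), a text .hea header and a MIT-format .atr beat annotation file.
#    Only what the package itself writes is guaranteed to round-trip; the
#    reader handles single-channel format-16 records with standard headers.

#' Write an ECG record as CSV + JSON sidecar
#'
#' @param record An `ecg_record`.
#' @param path_prefix Files `<prefix>.csv` (columns `sample`, `mV`) and
#'   `<prefix>.json` (`fs`, `r_peaks`, `labels`, `symbols`, `record_id`) are
#'   written.
#' @return `path_prefix`, invisibly.
#' @export
write_record_csv <- function(record, path_prefix) {
  stopifnot(inherits(record, "ecg_record"))
  write.csv(data.frame(sample = seq_along(record$signal) - 1L,
                       mV = record$signal),
            paste0(path_prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(record_id = record$record_id, fs = record$fs,
         r_peaks = record$r_peaks, labels = record$beat_labels,
         symbols = record$symbols),
    paste0(path_prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path_prefix)
}

#' Read an ECG record from CSV + JSON sidecar
#'
#' @param path_prefix Prefix used by [write_record_csv()].
#' @return An `ecg_record`.
#' @export
read_record_csv <- function(path_prefix) {
  csv <- paste0(path_prefix, ".csv")
  js <- paste0(path_prefix, ".json")
  if (!file.exists(csv) || !file.exists(js)) {
    stop("missing record files: ", path_prefix, ".{csv,json}")
  }
  sig <- read.csv(csv)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  structure(
    list(signal = sig$mV, fs = as.numeric(meta$fs),
         r_peaks = as.integer(meta$r_peaks),
         beat_labels = meta$labels, symbols = meta$symbols,
         record_id = meta$record_id %||% basename(path_prefix)),
    class = "ecg_record"
  )
}

# MIT annotation codes for the beat symbols this package handles.
WFDB_ANN_CODES <- c(
  N = 1L, L = 2L, R = 3L, a = 4L, V = 5L, F = 6L, J = 7L, A = 8L,
  S = 9L, E = 10L, j = 11L, "/" = 12L, Q = 13L, e = 34L, f = 38L
)

#' Write an ECG record in a minimal WFDB subset
#'
#' Emits `<name>.hea` (text header), `<name>.dat` (format 16: 16-bit
#' little-endian samples at 200 adu/mV) and `<name>.atr` (MIT annotation
#' format) into `dir`.
#'
#' @param record An `ecg_record`.
#' @param dir Output directory.
#' @param name Record name; defaults to the record id.
#' @return The header path, invisibly.
#' @export
write_wfdb <- function(record, dir, name = record$record_id) {
  stopifnot(inherits(record, "ecg_record"))
  gain <- 200
  adu <- as.integer(round(record$signal * gain))
  adu <- pmax(pmin(adu, 32767L), -32768L)
  hea <- file.path(dir, paste0(name, ".hea"))
  writeLines(c(
    sprintf("%s 1 %g %d", name, record$fs, length(adu)),
    sprintf("%s.dat 16 %d(0)/mV 16 0 %d 0 0 ECG", name, gain, adu[1])
  ), hea)
  writeBin(adu, file.path(dir, paste0(name, ".dat")), size = 2,
           endian = "little")
  # annotations: 2-byte entries, high 6 bits = code, low 10 bits = time
  # increment; increments > 1023 are carried by a SKIP (59) + 4-byte offset.
  con <- file(file.path(dir, paste0(name, ".atr")), "wb")
  on.exit(close(con))
  prev <- 0L
  for (k in seq_along(record$r_peaks)) {
    dt <- record$r_peaks[k] - prev
    prev <- record$r_peaks[k]
    code <- WFDB_ANN_CODES[[record$symbols[k]]]
    if (is.null(code)) stop("no WFDB code for symbol ", record$symbols[k])
    if (dt > 1023L) {
      writeBin(as.integer(bitwShiftL(59L, 10L)), con, size = 2,
               endian = "little")
      writeBin(c(bitwShiftR(dt, 16L), bitwAnd(dt, 65535L)), con, size = 2,
               endian = "little")
      dt <- 0L
    }
    writeBin(as.integer(bitwShiftL(code, 10L) + dt), con, size = 2,
             endian = "little")
  }
  writeBin(0L, con, size = 2, endian = "little")
  invisible(hea)
}

#' Read a WFDB record with beat annotations
#'
#' Reads the subset of the WFDB format written by [write_wfdb()]:
#' single-channel (the first channel of a multi-channel record), format 16,
#' with a MIT-format `.atr` annotation file. Annotation codes are converted
#' back to symbols and mapped to AAMI classes.
#'
#' @param path Path to the record, with or without the `.hea` extension.
#' @return An `ecg_record`.
#' @export
read_wfdb_record <- function(path) {
  base <- sub("\\.hea$", "", path)
  hea <- paste0(base, ".hea")
  dat <- paste0(base, ".dat")
  atr <- paste0(base, ".atr")
  for (f in c(hea, dat, atr)) {
    if (!file.exists(f)) stop("missing WFDB file: ", f)
  }
  hdr <- readLines(hea, warn = FALSE)
  top <- strsplit(trimws(hdr[1]), "\\s+")[[1]]
  if (length(top) < 3) stop("unreadable WFDB header: ", hea)
  fs <- as.numeric(top[3])
  n_sig <- as.integer(top[2])
  sig_line <- strsplit(trimws(hdr[2]), "\\s+")[[1]]
  if (sig_line[2] != "16") stop("only format-16 .dat files are supported")
  gain <- as.numeric(sub("\\(.*$", "", sig_line[3]))
  if (!is.finite(gain) || gain == 0) gain <- 200
  raw_n <- file.size(dat) / 2
  adu <- readBin(dat, integer(), n = raw_n, size = 2, endian = "little")
  if (n_sig > 1) adu <- adu[seq(1, length(adu), by = n_sig)]
  signal <- adu / gain

  bytes <- readBin(atr, integer(), n = file.size(atr) / 2, size = 2,
                   signed = FALSE, endian = "little")
  t_cur <- 0L
  peaks <- integer(0)
  symbols <- character(0)
  code_to_symbol <- stats::setNames(names(WFDB_ANN_CODES), WFDB_ANN_CODES)
  i <- 1L
  while (i <= length(bytes)) {
    word <- bytes[i]
    code <- bitwShiftR(word, 10L)
    dt <- bitwAnd(word, 1023L)
    if (code == 0L && dt == 0L) break
    if (code == 59L) {
      t_cur <- t_cur + bitwShiftL(bytes[i + 1L], 16L) + bytes[i + 2L]
      i <- i + 3L
      next
    }
    t_cur <- t_cur + dt
    sym <- code_to_symbol[[as.character(code)]]
    if (!is.null(sym)) {
      peaks <- c(peaks, t_cur)
      symbols <- c(symbols, sym)
    }
    i <- i + 1L
  }
  if (length(peaks) == 0) stop("no annotations in ", atr)
  structure(
    list(signal = signal, fs = fs, r_peaks = peaks,
         beat_labels = map_annotation_to_aami(symbols), symbols = symbols,
         record_id = basename(base)),
    class = "ecg_record"
  )
}
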