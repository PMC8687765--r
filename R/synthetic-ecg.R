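#' Rhythm specification for the synthetic ECG generator
#'
#' Describes a beat-label grammar and pacing for one simulated record. Named
#' rhythms follow the clinical definitions: bigeminy alternates a normal beat
#' with a premature one (`N-V-N-V-...` ventricular, `N-S-N-S-...` atrial),
#' trigeminy inserts a premature beat after every two normal beats
#' (`N-N-V-...` / `N-N-S-...`), and ventricular / atrial tachycardia are runs
#' of consecutive premature beats (`V-V-V-...` / `S-S-S-...`).
#'
#' @param name One of `"ventricular_bigeminy"`, `"atrial_bigeminy"`,
#'   `"ventricular_trigeminy"`, `"atrial_trigeminy"`,
#'   `"ventricular_tachycardia"`, `"atrial_tachycardia"`, `"normal_sinus"`,
#'   `"custom"`.
#' @param n_beats Number of beats to emit (>= 1). The repeating unit is
#'   truncated if `n_beats` is not a multiple of its length.
#' @param heart_rate_bpm Base heart rate in beats per minute.
#' @param rate_jitter_frac Uniform fractional jitter applied to each inter-beat
#'   interval, in `[0, 1)`.
#' @param custom_pattern Character vector of AAMI labels; required (and only
#'   allowed) when `name = "custom"`.
#' @return An object of class `rhythm_spec`.
#' @export
#' @examples
#' rhythm_spec("ventricular_bigeminy", n_beats = 6)
rhythm_spec <- function(name, n_beats,
                        heart_rate_bpm = 75,
                        rate_jitter_frac = 0,
                        custom_pattern = NULL) {
  known <- c(
    "ventricular_bigeminy", "atrial_bigeminy",
    "ventricular_trigeminy", "atrial_trigeminy",
    "ventricular_tachycardia", "atrial_tachycardia",
    "normal_sinus", "custom"
  )
  if (!is.character(name) || length(name) != 1 || !name %in% known) {
    stop("unknown rhythm name: ", paste(name, collapse = ", "))
  }
  if (!is.numeric(n_beats) || length(n_beats) != 1 || n_beats < 1) {
    stop("n_beats must be a positive integer")
  }
  if (heart_rate_bpm <= 0) stop("heart_rate_bpm must be positive")
  if (rate_jitter_frac < 0 || rate_jitter_frac >= 1) {
    stop("rate_jitter_frac must lie in [0, 1)")
  }
  if (name == "custom") {
    if (is.null(custom_pattern) || length(custom_pattern) == 0) {
      stop("custom rhythm requires a nonempty custom_pattern")
    }
    if (!all(custom_pattern %in% aami_classes)) {
      stop("custom_pattern labels must be AAMI classes (N, S, V, F, Q)")
    }
  } else if (!is.null(custom_pattern)) {
    stop("custom_pattern is only allowed with name = 'custom'")
  }
  structure(
    list(
      name = name, n_beats = as.integer(n_beats),
      heart_rate_bpm = heart_rate_bpm,
      rate_jitter_frac = rate_jitter_frac,
      custom_pattern = custom_pattern
    ),
    class = "rhythm_spec"
  )
}

#' Noise specification for the synthetic ECG generator
#'
#' Three additive noise components emulating the usual contaminants of a
#' clinical recording: low-frequency baseline wander, powerline (mains)
#' interference, and broadband muscle/equipment noise.
#'
#' @param baseline_wander_amp Amplitude (mV) of the sinusoidal baseline drift.
#' @param baseline_wander_freq Drift frequency in Hz.
#' @param powerline_amp Amplitude (mV) of mains interference.
#' @param powerline_freq Mains frequency: 50 or 60 Hz.
#' @param gaussian_sd Standard deviation (mV) of white Gaussian noise.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(baseline_wander_amp = 0.15, baseline_wander_freq = 0.3,
                       powerline_amp = 0.05, powerline_freq = 50,
                       gaussian_sd = 0.03) {
  if (baseline_wander_amp < 0 || powerline_amp < 0 || gaussian_sd < 0) {
    stop("noise amplitudes must be nonnegative")
  }
  if (!powerline_freq %in% c(50, 60)) stop("powerline_freq must be 50 or 60 Hz")
  structure(
    list(
      baseline_wander_amp = baseline_wander_amp,
      baseline_wander_freq = baseline_wander_freq,
      powerline_amp = powerline_amp,
      powerline_freq = powerline_freq,
      gaussian_sd = gaussian_sd
    ),
    class = "noise_spec"
  )
}

rhythm_unit <- function(spec) {
  switch(spec$name,
    ventricular_bigeminy = c("N", "V"),
    atrial_bigeminy = c("N", "S"),
    ventricular_trigeminy = c("N", "N", "V"),
    atrial_trigeminy = c("N", "N", "S"),
    ventricular_tachycardia = "V",
    atrial_tachycardia = "S",
    normal_sinus = "N",
    custom = spec$custom_pattern
  )
}

#' Expand a rhythm specification into its beat-label sequence
#'
#' Deterministically repeats the rhythm's unit (e.g. `c("N","V")` for
#' ventricular bigeminy) until `n_beats` labels have been produced, truncating
#' the final repeat if necessary.
#'
#' @param spec A [rhythm_spec()].
#' @return Character vector of `spec$n_beats` AAMI labels.
#' @export
#' @examples
#' generate_rhythm_labels(rhythm_spec("ventricular_trigeminy", n_beats = 9))
generate_rhythm_labels <- function(spec) {
  stopifnot(inherits(spec, "rhythm_spec"))
  unit <- rhythm_unit(spec)
  rep_len(unit, spec$n_beats)
}

# Gaussian bump; mu/sd in seconds relative to the R peak, amp in mV.
gauss_bump <- function(tau, mu, sd, amp) amp * exp(-((tau - mu)^2) / (2 * sd^2))

#' Beat-window geometry
#'
#' The fixed beat window extends 0.25 s before and 0.40 s after the R peak,
#' i.e. `round(0.25 fs)` samples before the peak sample and `round(0.4 fs)`
#' after it. At 360 Hz this is 90 + 1 + 144 = 235 samples with the R peak at
#' 0-based index 90.
#'
#' @param fs Sampling rate in Hz.
#' @return List with `before`, `after`, `length`, `r_index` (0-based position
#'   of the R peak inside the window).
#' @export
beat_window <- function(fs) {
  if (fs <= 0) stop("fs must be positive")
  before <- round(0.25 * fs)
  after <- round(0.4 * fs)
  list(before = before, after = after, length = before + 1L + after,
       r_index = before)
}

# Class-specific morphology parameters. Each beat is a parametric sum of
# Gaussian bumps for the P, Q, R, S and T deflections; classes differ in which
# bumps exist and in their widths/amplitudes:
#   N: P wave + narrow QRS + T
#   V: wide, large QRS, no P, discordant T
#   S: early, peaked/abnormal P, narrow QRS (premature atrial origin)
#   F: morphology intermediate between N and V (fusion beat)
#   Q: pacing-spike-like artifact followed by a wide evoked QRS (a stand-in;
#      no physiological reference defines the "unclassifiable" morphology)
beat_morphology <- function(label) {
  switch(label,
    N = list(
      bumps = list(
        c(-0.17, 0.022, 0.12),   # P
        c(-0.025, 0.008, -0.10), # Q
        c(0.000, 0.012, 1.00),   # R
        c(0.028, 0.009, -0.18),  # S
        c(0.190, 0.050, 0.30)    # T
      )
    ),
    S = list(
      # nearly normal morphology: an atrial premature beat conducts through
      # the ventricles normally, so only the P wave differs subtly — the
      # reliable cue is prematurity, i.e. rhythm context, not shape
      bumps = list(
        c(-0.175, 0.020, 0.15),  # marginally early, marginally peaked P
        c(-0.025, 0.008, -0.10),
        c(0.000, 0.012, 1.00),
        c(0.028, 0.009, -0.18),
        c(0.190, 0.050, 0.30)
      )
    ),
    V = list(
      bumps = list(
        c(-0.010, 0.045, 1.10),  # wide dominant deflection, no P
        c(0.075, 0.050, -0.45),  # slurred opposite lobe
        c(0.230, 0.060, -0.35)   # discordant T
      )
    ),
    F = NULL, # handled as a blend of N and V below
    Q = list(
      bumps = list(
        c(-0.040, 0.003, 0.85),  # pacing spike
        c(0.010, 0.040, 0.90),   # wide evoked complex
        c(0.090, 0.045, -0.35),
        c(0.230, 0.055, 0.25)
      )
    ),
    stop("unknown AAMI label: ", label)
  )
}

beat_shape <- function(label, tau) {
  if (label == "F") {
    return(0.5 * beat_shape("N", tau) + 0.5 * beat_shape("V", tau))
  }
  m <- beat_morphology(label)
  y <- numeric(length(tau))
  for (b in m$bumps) y <- y + gauss_bump(tau, b[1], b[2], b[3])
  y
}

#' Generate one synthetic beat waveform
#'
#' Produces the fixed-length beat window for one AAMI class as a sum of
#' Gaussian deflections (P, QRS, T), with small random amplitude/width
#' variation so repeated beats are not identical. Deterministic given
#' `(label, fs, seed)`.
#'
#' @param label AAMI class, one of `aami_classes`.
#' @param fs Sampling rate in Hz (must be positive).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   consumed instead.
#' @param variability Fractional scale of the per-beat random amplitude and
#'   width perturbation.
#' @return Numeric vector of `beat_window(fs)$length` samples (mV).
#' @export
generate_beat_waveform <- function(label, fs = 360, seed = NULL,
                                   variability = 0.05) {
  if (fs <= 0) stop("fs must be positive")
  if (!label %in% aami_classes) stop("unknown AAMI label: ", label)
  bw <- beat_window(fs)
  tau <- (seq_len(bw$length) - 1L - bw$r_index) / fs
  gen <- function() {
    amp_scale <- 1 + rnorm(1, 0, variability)
    width_scale <- 1 + rnorm(1, 0, variability / 2)
    amp_scale * beat_shape(label, tau / width_scale)
  }
  if (is.null(seed)) gen() else with_local_seed(seed, gen())
}

# Inter-beat intervals in seconds. A premature beat (S or V) arrives early:
# the interval *ending* at it is shortened by `premature_frac`, and the
# following interval is lengthened so that on average the base rate holds
# (compensatory pause).
beat_intervals <- function(labels, heart_rate_bpm, jitter_frac,
                           premature_frac = 0.7) {
  base <- 60 / heart_rate_bpm
  n <- length(labels)
  iv <- rep(base, n) # iv[k] = interval preceding beat k (iv[1] = lead-in)
  if (n >= 2) {
    for (k in 2:n) {
      if (labels[k] %in% c("S", "V")) iv[k] <- premature_frac * base
      else if (labels[k - 1] %in% c("S", "V")) iv[k] <- (2 - premature_frac) * base
    }
  }
  if (jitter_frac > 0) iv <- iv * (1 + runif(n, -jitter_frac, jitter_frac))
  iv
}

synthesize_noise <- function(n, fs, noise, phases, eps) {
  t_sec <- (seq_len(n) - 1) / fs
  noise$baseline_wander_amp *
    sin(2 * pi * noise$baseline_wander_freq * t_sec + phases[1]) +
    noise$powerline_amp *
      sin(2 * pi * noise$powerline_freq * t_sec + phases[2]) +
    noise$gaussian_sd * eps
}

#' Generate a complete synthetic ECG record
#'
#' Lays the rhythm's beat waveforms on a time axis at intervals of
#' `60 / heart_rate_bpm` seconds (premature S/V beats arrive early, followed by
#' a compensatory pause), sums them where windows overlap, and adds the three
#' noise components. Records the true R-peak sample indices (0-based) and
#' per-beat AAMI labels. Fully reproducible from `seed`.
#'
#' @param rhythm A [rhythm_spec()].
#' @param noise A [noise_spec()]; use `noise_spec(0, gaussian_sd = 0,
#'   powerline_amp = 0)` for a clean record.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param record_id Identifier stored with the record.
#' @return An object of class `ecg_record`: a list with `signal` (mV), `fs`,
#'   `r_peaks` (0-based sample indices), `beat_labels`, `symbols` (MIT-BIH
#'   style annotation characters) and `record_id`.
#' @export
#' @examples
#' rec <- generate_record(rhythm_spec("ventricular_bigeminy", 10),
#'                        noise_spec(), seed = 1)
#' length(rec$r_peaks)
generate_record <- function(rhythm, noise = noise_spec(), fs = 360, seed = 1,
                            record_id = paste0("synth-", rhythm$name, "-", seed)) {
  stopifnot(inherits(rhythm, "rhythm_spec"), inherits(noise, "noise_spec"))
  if (fs <= 0) stop("fs must be positive")
  labels <- generate_rhythm_labels(rhythm)
  bw <- beat_window(fs)

  with_local_seed(seed, {
    iv <- beat_intervals(labels, rhythm$heart_rate_bpm, rhythm$rate_jitter_frac)
    # first peak gets a fixed lead-in long enough for a full pre-window
    t_peaks <- cumsum(iv) - iv[1] + (bw$before + 10) / fs
    r_peaks <- round(t_peaks * fs)
    n <- max(r_peaks) + bw$after + 11L
    clean <- numeric(n)
    for (k in seq_along(labels)) {
      w <- generate_beat_waveform(labels[k], fs)
      idx <- (r_peaks[k] - bw$before):(r_peaks[k] + bw$after) + 1L
      clean[idx] <- clean[idx] + w
    }
    phases <- runif(2, 0, 2 * pi)
    eps <- rnorm(n)
    signal <- clean + synthesize_noise(n, fs, noise, phases, eps)

    structure(
      list(
        signal = signal, fs = fs,
        r_peaks = as.integer(r_peaks),
        beat_labels = labels,
        symbols = aami_to_symbol(labels),
        record_id = record_id
      ),
      class = "ecg_record"
    )
  })
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf(
    "<ecg_record %s: %d samples @ %g Hz, %d beats (%s)>\n",
    x$record_id, length(x$signal), x$fs, length(x$r_peaks),
    paste(names(table(x$beat_labels)), table(x$beat_labels),
          sep = "=", collapse = " ")
  ))
  invisible(x)
}

#' @export
as_tibble.ecg_record <- function(x, ...) {
  tibble::tibble(sample = seq_along(x$signal) - 1L, mV = x$signal)
}
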