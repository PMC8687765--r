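test_that("named rhythm grammars expand to their clinical repeating units", {
  cases <- list(
    list("ventricular_bigeminy", 6, c("N", "V", "N", "V", "N", "V")),
    list("atrial_bigeminy", 4, c("N", "S", "N", "S")),
    list("ventricular_trigeminy", 9,
         c("N", "N", "V", "N", "N", "V", "N", "N", "V")),
    list("atrial_trigeminy", 7, c("N", "N", "S", "N", "N", "S", "N")),
    list("ventricular_tachycardia", 3, c("V", "V", "V")),
    list("atrial_tachycardia", 3, c("S", "S", "S")),
    list("normal_sinus", 1, "N")
  )
  for (cs in cases) {
    expect_identical(
      generate_rhythm_labels(rhythm_spec(cs[[1]], cs[[2]])), cs[[3]],
      info = cs[[1]]
    )
  }
  expect_identical(
    generate_rhythm_labels(
      rhythm_spec("custom", 5, custom_pattern = c("Q", "F"))
    ),
    c("Q", "F", "Q", "F", "Q")
  )
})

test_that("invalid rhythm specifications are rejected", {
  expect_error(rhythm_spec("sinus_arrest", 5), "unknown rhythm")
  expect_error(rhythm_spec("custom", 5), "custom_pattern")
  expect_error(rhythm_spec("custom", 5, custom_pattern = character(0)),
               "custom_pattern")
  expect_error(rhythm_spec("normal_sinus", 0), "positive")
  expect_error(rhythm_spec("normal_sinus", 5, rate_jitter_frac = 1), "jitter")
  expect_error(noise_spec(gaussian_sd = -1), "nonnegative")
})

test_that("beat waveforms have the fixed window length and are seed-deterministic", {
  w <- generate_beat_waveform("N", fs = 360, seed = 1)
  expect_length(w, 235)
  expect_identical(w, generate_beat_waveform("N", fs = 360, seed = 1))
  w2 <- generate_beat_waveform("V", fs = 360, seed = 1)
  expect_identical(w2, generate_beat_waveform("V", fs = 360, seed = 1))
  # window rule generalizes across sampling rates
  expect_length(generate_beat_waveform("N", fs = 250, seed = 1),
                round(0.25 * 250) + 1 + round(0.4 * 250))
  expect_error(generate_beat_waveform("N", fs = 0), "positive")
  expect_error(generate_beat_waveform("X", fs = 360), "unknown")
})

test_that("ventricular beats have wider QRS complexes than normal beats", {
  half_max_width <- function(w) {
    r <- which.max(abs(w))
    sum(abs(w) > abs(w[r]) / 2 & seq_along(w) %in% (r - 40):(r + 40))
  }
  widths <- vapply(1:100, function(s) {
    c(half_max_width(generate_beat_waveform("N", 360, seed = s)),
      half_max_width(generate_beat_waveform("V", 360, seed = s)))
  }, numeric(2))
  expect_gt(mean(widths[2, ]), mean(widths[1, ]))
})

test_that("records conserve beat counts and annotate true R peaks", {
  rec <- generate_record(rhythm_spec("ventricular_bigeminy", 100),
                         noise_spec(), seed = 3)
  expect_length(rec$r_peaks, 100)
  expect_length(rec$beat_labels, 100)
  expect_true(all(diff(rec$r_peaks) > 0))
  expect_true(all(rec$r_peaks >= 0 & rec$r_peaks < length(rec$signal)))
})

test_that("records are bit-identical under the same seed", {
  spec <- rhythm_spec("atrial_trigeminy", 30, rate_jitter_frac = 0.05)
  r1 <- generate_record(spec, noise_spec(), seed = 11)
  r2 <- generate_record(spec, noise_spec(), seed = 11)
  expect_identical(r1$signal, r2$signal)
  expect_identical(r1$r_peaks, r2$r_peaks)
})

test_that("inter-beat intervals follow the rate and prematurity rules", {
  # sinus at 60 bpm, no jitter: every gap exactly 360 samples
  rec <- clean_record(20, "normal_sinus", heart_rate_bpm = 60)
  expect_true(all(diff(rec$r_peaks) == 360L))
  # bigeminy: premature V arrives at 0.7x the base interval, then a
  # compensatory pause of 1.3x
  recb <- clean_record(21, "ventricular_bigeminy", heart_rate_bpm = 60)
  gaps <- diff(recb$r_peaks)
  expect_true(all(gaps[seq(1, length(gaps), by = 2)] == 252L)) # into V
  expect_true(all(gaps[seq(2, length(gaps), by = 2)] == 468L)) # after V
})

test_that("noise is purely additive on top of the clean beat train", {
  spec <- rhythm_spec("normal_sinus", 15)
  clean <- generate_record(spec, noise_spec(0, powerline_amp = 0,
                                            gaussian_sd = 0), seed = 9)
  wander <- generate_record(spec,
                            noise_spec(baseline_wander_amp = 0.25,
                                       baseline_wander_freq = 0.3,
                                       powerline_amp = 0, gaussian_sd = 0),
                            seed = 9)
  expect_identical(clean$r_peaks, wander$r_peaks)
  d <- wander$signal - clean$signal
  # the difference must be exactly the 0.3 Hz sinusoid: project onto the
  # sin/cos pair at that frequency and check the residual vanishes
  tt <- (seq_along(d) - 1) / clean$fs
  base <- cbind(sin(2 * pi * 0.3 * tt), cos(2 * pi * 0.3 * tt))
  resid <- stats::lm.fit(base, d)$residuals
  expect_lt(max(abs(resid)), 1e-10)
  expect_equal(sqrt(sum(stats::lm.fit(base, d)$coefficients^2)), 0.25,
               tolerance = 1e-10)
})
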