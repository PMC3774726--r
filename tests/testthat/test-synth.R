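test_that("beat count and spacing follow the requested heart rate", {
  syn <- clean_syn(duration_s = 30, bpm = 60, fs = 360, seed = 1)
  expect_length(syn$true_r_peaks, 30)
  expect_equal(unique(diff(syn$true_r_peaks)), 360L)
  expect_length(syn$record$samples, 30 * 360)

  for (bpm in c(45, 90, 150)) {
    syn <- clean_syn(duration_s = 30, bpm = bpm, seed = 2)
    expect_lte(abs(length(syn$true_r_peaks) - bpm / 60 * 30), 1)
  }
})

test_that("generation is deterministic for a fixed seed", {
  spec <- synthetic_spec(duration_s = 10, muscle_noise_sd = 0.1,
                         rr_jitter_sd_ms = 20, seed = 99)
  a <- generate_ecg(spec)
  b <- generate_ecg(spec)
  expect_identical(a$record$samples, b$record$samples)
  expect_identical(a$true_r_peaks, b$true_r_peaks)

  c_ <- generate_ecg(synthetic_spec(duration_s = 10, muscle_noise_sd = 0.1,
                                    rr_jitter_sd_ms = 20, seed = 100))
  expect_false(identical(a$record$samples, c_$record$samples))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(generate_ecg(synthetic_spec(duration_s = 5, seed = 7,
                                        muscle_noise_sd = 0.1)))
  expect_identical(rnorm(1), before)
})

test_that("mains contamination shows as a sharp 60 Hz spectral peak", {
  fs <- 360
  syn <- generate_ecg(synthetic_spec(fs = fs, duration_s = 30,
                                     mains_60hz_amp = 0.2, seed = 4))
  x <- syn$record$samples
  p <- Mod(stats::fft(x))^2
  freq <- (seq_along(p) - 1) * fs / length(p)
  peak_bin <- which.min(abs(freq - 60))
  peak <- max(p[(peak_bin - 1):(peak_bin + 1)])
  neigh <- c(which(freq >= 55 & freq <= 58), which(freq >= 62 & freq <= 65))
  expect_gte(peak / max(p[neigh]), 10)
})

test_that("jitter preserves beat ordering and stays truncated", {
  syn <- generate_ecg(synthetic_spec(duration_s = 30, rr_jitter_sd_ms = 30,
                                     seed = 5))
  rr <- diff(syn$true_r_peaks) / 360 * 1000
  expect_true(all(rr > 0))
  # RR = 1000 ms +/- jitter, jitter truncated at 3 sigma on each beat
  expect_true(all(abs(rr - 1000) <= 2 * 3 * 30 + 10))
})

test_that("inverted QRS polarity does not cost sensitivity", {
  syn <- generate_ecg(synthetic_spec(duration_s = 20, inverted_qrs = TRUE,
                                     seed = 6))
  ev <- evaluate_detection(detect_qrs(syn$record)$r_peaks,
                           syn$true_r_peaks, fs = 360)
  expect_equal(ev$se_percent, 100)
})

test_that("the same spec rendered at two rates keeps beat times", {
  a <- generate_ecg(synthetic_spec(duration_s = 20, fs = 250,
                                   rr_jitter_sd_ms = 15, seed = 8))
  b <- generate_ecg(synthetic_spec(duration_s = 20, fs = 1000,
                                   rr_jitter_sd_ms = 15, seed = 8))
  expect_length(a$true_r_peaks, length(b$true_r_peaks))
  ta <- (a$true_r_peaks - 1) / 250
  tb <- (b$true_r_peaks - 1) / 1000
  expect_lte(max(abs(ta - tb)), 1 / 250)
})

test_that("a heart-rate ramp spans the requested range", {
  syn <- generate_ecg(synthetic_spec(duration_s = 60,
                                     heart_rate_bpm = c(60, 120), seed = 9))
  rr <- diff(syn$true_r_peaks) / 360
  expect_gt(60 / rr[length(rr)], 60 / rr[1])   # rate increases
  expect_gt(length(syn$true_r_peaks), 60)      # more than 60 bpm average
})

test_that("invalid specs are rejected with descriptive errors", {
  expect_error(synthetic_spec(heart_rate_bpm = 10), "\\[20, 300\\]")
  expect_error(synthetic_spec(duration_s = -1), "positive")
  expect_error(synthetic_spec(mains_harmonic_amps = 1), "length 2")
  expect_error(synthetic_spec(baseline_wander_hz = 2), "\\(0, 1\\)")
  expect_error(synthetic_spec(qrs_amp = Inf), "finite")
})
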