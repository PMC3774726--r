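test_that("durations convert to the published sample counts at 360 Hz", {
  expect_identical(duration_to_samples(97, 360), 35L)
  expect_identical(duration_to_samples(611, 360), 220L)
  expect_identical(duration_to_samples(1000, 360), 360L)
  expect_identical(duration_to_samples(120, 360), 43L)
  expect_identical(duration_to_samples(80, 360), 29L)
  # odd mode bumps even counts up by one
  expect_identical(duration_to_samples(611, 360, mode = "odd"), 221L)
  expect_identical(duration_to_samples(97, 360, mode = "odd"), 35L)
  expect_identical(duration_to_samples(0.1, 360), 1L)
  expect_error(duration_to_samples(-5, 360), "positive")
  expect_error(duration_to_samples(97, 0), "positive")
})

test_that("moving average matches the explicit-sum oracle and edge rules", {
  expect_equal(moving_average(rep(3.5, 50), 7), rep(3.5, 50))
  expect_equal(moving_average(rep(3.5, 50), 8), rep(3.5, 50))

  imp <- numeric(101); imp[51] <- 1
  ma <- moving_average(imp, 5)
  expect_equal(ma[49:53], rep(1 / 5, 5))
  expect_equal(sum(ma != 0), 5)

  set.seed(1)
  for (w in c(1, 2, 4, 5, 35, 200)) {
    x <- rnorm(200)
    expect_equal(moving_average(x, w), ma_oracle(x, w), tolerance = 1e-10)
  }
  expect_error(moving_average(rnorm(10), 11), "exceeds")
  expect_error(moving_average(rnorm(10), 0), ">= 1")
})

test_that("offset is the beta fraction of the mean squared signal", {
  expect_equal(compute_offset(2.5, 0.08), 0.2)
  expect_equal(compute_offset(123.4, 0), 0)
  expect_error(compute_offset(-1, 0.5), ">= 0")
  expect_error(compute_offset(1, 1.5), "\\[0, 1\\]")
})

test_that("block generation matches a per-sample scan oracle", {
  # nothing above threshold
  ma <- list(ma_qrs = rep(0.1, 50), ma_beat = rep(0.5, 50))
  expect_identical(nrow(generate_blocks(ma, 0)), 0L)

  # single constructed block [100, 140)
  qrs <- numeric(300); qrs[100:139] <- 1
  ma <- list(ma_qrs = qrs, ma_beat = rep(0.3, 300))
  b <- generate_blocks(ma, 0)
  expect_equal(nrow(b), 1L)
  expect_equal(b$onset, 100L)
  expect_equal(b$end, 140L)
  expect_equal(b$width, 40L)
  expect_false(any(b$accepted))

  set.seed(2)
  for (i in 1:50) {
    n <- sample(50:300, 1)
    maq <- cumsum(rnorm(n)); mab <- cumsum(rnorm(n))
    off <- runif(1, -1, 1)
    got <- generate_blocks(list(ma_qrs = maq, ma_beat = mab), off)
    want <- blocks_oracle(maq, mab, off)
    expect_equal(got$onset, want$onset)
    expect_equal(got$end, want$end)
    expect_equal(got$width, want$width)
  }
})

test_that("width acceptance is greater-than-or-equal at W1", {
  mk <- function(widths) {
    data.frame(onset = cumsum(c(1, widths[-length(widths)] + 5)),
               end = cumsum(c(1, widths[-length(widths)] + 5)) + widths,
               width = widths, accepted = FALSE)
  }
  b <- threshold_blocks(mk(c(34, 35, 36)), 35L)
  expect_equal(b$accepted, c(FALSE, TRUE, TRUE))
  b <- threshold_blocks(mk(c(10, 35, 200)), 35L)
  expect_equal(b$accepted, c(FALSE, TRUE, TRUE))
})

test_that("R peak is the max absolute filtered value, ties to earliest", {
  filt <- numeric(30)
  filt[13] <- 2; filt[16] <- 1
  b <- data.frame(onset = 10L, end = 20L, width = 10L, accepted = TRUE)
  expect_identical(locate_r_peaks(b, filt), 13L)

  filt <- numeric(30); filt[12] <- -5; filt[15] <- 4
  expect_identical(locate_r_peaks(b, filt), 12L)

  filt <- numeric(30); filt[11] <- 3; filt[14] <- -3   # tie on |.|
  expect_identical(locate_r_peaks(b, filt), 11L)

  set.seed(3)
  for (i in 1:50) {
    filt <- rnorm(200)
    onsets <- sort(sample(1:150, 4))
    b <- data.frame(onset = onsets, end = onsets + 20L, width = 20L,
                    accepted = c(TRUE, FALSE, TRUE, TRUE))
    expect_identical(locate_r_peaks(b, filt), argmax_oracle(b, filt))
  }
})

test_that("full detection finds every beat of a clean synthetic record", {
  syn <- clean_syn(duration_s = 30, bpm = 60, fs = 360, seed = 10)
  det <- detect_qrs(syn$record)
  expect_length(det$r_peaks, 30)
  m <- match_beats(det$r_peaks, syn$true_r_peaks,
                   tolerance_samples = round(0.010 * 360))
  expect_equal(m$tp, 30)   # every R within 10 ms of truth
})

test_that("detections are invariant to amplitude scaling and DC shifts", {
  syn <- clean_syn(duration_s = 20, bpm = 72, seed = 11,
                   muscle_noise_sd = 0.05)
  base <- detect_qrs(syn$record)$r_peaks
  scaled <- detect_qrs(ecg_record(10 * syn$record$samples, 360))$r_peaks
  expect_identical(scaled, base)
  tiny <- detect_qrs(ecg_record(0.01 * syn$record$samples, 360))$r_peaks
  expect_identical(tiny, base)
  shifted <- detect_qrs(ecg_record(syn$record$samples + 7.5, 360))$r_peaks
  expect_identical(shifted, base)
})

test_that("the same beat train is found at different sampling rates", {
  s250 <- clean_syn(duration_s = 30, fs = 250, seed = 5)
  s500 <- clean_syn(duration_s = 30, fs = 500, seed = 5)
  d250 <- detect_qrs(s250$record)$r_peaks
  d500 <- detect_qrs(s500$record)$r_peaks
  expect_length(d250, length(d500))
  t250 <- (d250 - 1) / 250
  t500 <- (d500 - 1) / 500
  expect_lt(max(abs(t250 - t500)), 0.005)
})

test_that("accepted blocks are at least W1 wide and contain their peak", {
  syn <- clean_syn(duration_s = 20, seed = 12, muscle_noise_sd = 0.2)
  det <- detect_qrs(syn$record)
  acc <- det$blocks[det$blocks$accepted, ]
  expect_true(all(acc$width >= det$w1_samples))
  expect_length(det$r_peaks, nrow(acc))
  expect_true(all(det$r_peaks >= acc$onset & det$r_peaks < acc$end))
  expect_false(is.unsorted(det$r_peaks, strictly = TRUE))
})

test_that("raising beta never widens total block coverage", {
  syn <- clean_syn(duration_s = 20, seed = 13, muscle_noise_sd = 0.1)
  pp <- preprocess_ecg(syn$record, detector_params())
  ma <- event_moving_averages(pp$squared, detector_params(), 360)
  coverage <- vapply(seq(0, 0.1, by = 0.02), function(beta) {
    b <- generate_blocks(ma, compute_offset(pp$mean_squared, beta))
    sum(b$width)
  }, numeric(1))
  expect_true(all(diff(coverage) <= 0))
})

test_that("records shorter than one beat-scale window are refused", {
  short <- ecg_record(rnorm(100), 360)   # 0.28 s < 611 ms
  expect_error(detect_qrs(short), "too short")
})
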