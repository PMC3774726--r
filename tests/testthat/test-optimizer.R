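make_corpus <- function(n = 3, duration_s = 12) {
  lapply(seq_len(n), function(s) clean_syn(duration_s = duration_s, seed = s))
}

test_that("a singleton grid reproduces a direct detect-and-evaluate call", {
  corpus <- make_corpus(2)
  g <- parameter_grid(f1_values = 8, f2_values = 20, w1_values = 97,
                      w2_values = 611, beta_values = 0.08)
  res <- brute_force_optimize(corpus, g)
  expect_equal(nrow(res), 1L)

  tp <- fp <- fn <- 0L
  for (entry in corpus) {
    det <- detect_qrs(entry$record)
    m <- match_beats(det$r_peaks, entry$true_r_peaks,
                     round(150 * entry$record$fs / 1000))
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
  }
  direct <- score_detection(tp, fp, fn)
  expect_equal(res$se_percent, direct$se_percent)
  expect_equal(res$pp_percent, direct$pp_percent)
  expect_equal(res$overall_percent, direct$overall_percent)
})

test_that("row count equals an independent nested-loop admissibility count", {
  g <- parameter_grid(f1_values = c(4, 8, 12), f2_values = c(10, 16, 20),
                      w1_values = c(97, 600), w2_values = c(400, 611),
                      beta_values = c(0, 0.08))
  combos <- grid_combinations(g)
  count <- 0L
  for (f1 in g$f1_values) for (f2 in g$f2_values)
    for (w1 in g$w1_values) for (w2 in g$w2_values)
      for (b in g$beta_values) {
        if (f1 < f2 && w1 < w2) count <- count + 1L
      }
  expect_equal(nrow(combos), count)
  expect_equal(nrow(combos) + attr(combos, "n_skipped"),
               3 * 3 * 2 * 2 * 2)

  corpus <- make_corpus(1, duration_s = 8)
  res <- brute_force_optimize(corpus, g)
  expect_equal(nrow(res), count)
})

test_that("results are sorted best-first by overall accuracy", {
  corpus <- make_corpus(2, duration_s = 10)
  g <- parameter_grid(f1_values = c(1, 8), f2_values = c(12, 20),
                      w1_values = c(97, 300), w2_values = 611,
                      beta_values = c(0, 0.08))
  res <- brute_force_optimize(corpus, g)
  ov <- res$overall_percent
  defined <- ov[!is.na(ov)]
  expect_true(all(diff(defined) <= 0))
  expect_true(all(defined[1] >= defined))
  if (anyNA(ov)) {   # undefined scores rank strictly last
    expect_gt(min(which(is.na(ov))), max(which(!is.na(ov))))
  }
  expect_equal(res$combination, seq_len(nrow(res)))
})

test_that("a grid containing the generating parameters is recovered", {
  corpus <- make_corpus(3, duration_s = 12)
  g <- parameter_grid(f1_values = c(1, 8), f2_values = c(20, 25),
                      w1_values = c(97, 160), w2_values = c(555, 611),
                      beta_values = c(0.02, 0.08))
  res <- brute_force_optimize(corpus, g)
  expect_equal(res$se_percent[1], 100)
  expect_equal(res$pp_percent[1], 100)
  expect_equal(res$overall_percent[1], 100)
})

test_that("the top row does not depend on grid ordering", {
  corpus <- make_corpus(2, duration_s = 10)
  g1 <- parameter_grid(f1_values = c(1, 8), f2_values = c(12, 20),
                       w1_values = c(97, 160), w2_values = c(555, 611),
                       beta_values = c(0, 0.08))
  g2 <- parameter_grid(f1_values = c(8, 1), f2_values = c(20, 12),
                       w1_values = c(160, 97), w2_values = c(611, 555),
                       beta_values = c(0.08, 0))
  r1 <- brute_force_optimize(corpus, g1)
  r2 <- brute_force_optimize(corpus, g2)
  expect_equal(as.list(r1[1, -1]), as.list(r2[1, -1]))
  expect_equal(r1$overall_percent, r2$overall_percent)
})

test_that("empty admissible grids are refused", {
  g <- parameter_grid(f1_values = 20, f2_values = 10, w1_values = 97,
                      w2_values = 611, beta_values = 0.08)
  expect_error(brute_force_optimize(make_corpus(1, 8), g), "admissible")
  expect_error(brute_force_optimize(list(), parameter_grid()), "empty")
})

test_that("grid results export to a table-style CSV", {
  corpus <- make_corpus(1, duration_s = 8)
  g <- parameter_grid(f1_values = 8, f2_values = 20, w1_values = 97,
                      w2_values = 611, beta_values = 0.08)
  res <- brute_force_optimize(corpus, g)
  path <- tempfile(fileext = ".csv")
  write_grid_results(res, path)
  tab <- utils::read.csv(path, check.names = FALSE)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab[["Frequency Band"]], "8-20 Hz")
  expect_equal(tab[["Offset (%)"]], 8)
  expect_named(tab, c("Combination", "Frequency Band", "W1 (ms)", "W2 (ms)",
                      "Offset (%)", "SE (%)", "+P (%)",
                      "Overall Accuracy (%)"))
})
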