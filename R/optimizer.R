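#' Parameter grid for the brute-force search
#'
#' Value lists for the five detector parameters. The Cartesian product is
#' filtered to admissible combinations (`f1 < f2` and `w1 < w2`); the
#' skipped count is reported by [brute_force_optimize()]. The defaults
#' reconstruct the published search ranges: passband start 1-10 Hz, stop
#' 11-25 Hz, QRS window 55-111 ms (20-40 samples at 360 Hz), beat window
#' 555-694 ms (200-250 samples at 360 Hz), offset fraction 0-10%.
#'
#' @param f1_values,f2_values Passband start/stop candidate lists (Hz).
#' @param w1_values,w2_values Window duration candidate lists (ms).
#' @param beta_values Offset-fraction candidates in `[0, 1]`.
#' @return Object of class `parameter_grid`.
#' @examples
#' g <- parameter_grid(f1_values = 8, f2_values = 20,
#'                     w1_values = 97, w2_values = 611, beta_values = 0.08)
#' @export
parameter_grid <- function(f1_values = 1:10,
                           f2_values = 11:25,
                           w1_values = c(55.6, 69.4, 83.3, 97.2, 111.1),
                           w2_values = seq(555.6, 694.4, length.out = 6),
                           beta_values = seq(0, 0.10, by = 0.01)) {
  lists <- list(f1_values = as.numeric(f1_values),
                f2_values = as.numeric(f2_values),
                w1_values = as.numeric(w1_values),
                w2_values = as.numeric(w2_values),
                beta_values = as.numeric(beta_values))
  for (nm in names(lists)) {
    if (length(lists[[nm]]) == 0L || any(!is.finite(lists[[nm]]))) {
      stop(sprintf("`%s` must be a non-empty finite list", nm), call. = FALSE)
    }
  }
  if (any(lists$beta_values < 0 | lists$beta_values > 1)) {
    stop("`beta_values` must lie in [0, 1]", call. = FALSE)
  }
  structure(lists, class = "parameter_grid")
}

#' Enumerate admissible grid combinations
#'
#' Expands the full Cartesian product and keeps the admissible rows
#' (`f1 < f2`, `w1 < w2`).
#'
#' @param grid A [parameter_grid()].
#' @return Data frame with columns `f1`, `f2`, `w1_ms`, `w2_ms`, `beta`,
#'   one row per admissible combination, plus attribute `n_skipped`.
#' @export
grid_combinations <- function(grid) {
  stopifnot(inherits(grid, "parameter_grid"))
  full <- expand.grid(beta = grid$beta_values, w2_ms = grid$w2_values,
                      w1_ms = grid$w1_values, f2 = grid$f2_values,
                      f1 = grid$f1_values, KEEP.OUT.ATTRS = FALSE)
  full <- full[, c("f1", "f2", "w1_ms", "w2_ms", "beta")]
  ok <- full$f1 < full$f2 & full$w1_ms < full$w2_ms
  out <- full[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Brute-force optimization of the detector parameters
#'
#' Runs the detector over a corpus with every admissible parameter
#' combination, pools TP/FP/FN across records, scores SE, +P and overall
#' accuracy (their mean), and returns the table sorted by descending
#' overall accuracy — the first row is the optimum. Ties are broken by
#' higher SE, then lower `w1_ms`, lower `f1`, lower `f2`, lower `w2_ms`,
#' lower `beta`, giving a total order so the result is independent of grid
#' ordering. Preprocessing is cached per frequency band and moving
#' averages per window length, which keeps the exhaustive search tractable.
#'
#' @param corpus List of entries, each a list with `record` (an
#'   [ecg_record()]) and `reference` (true beat sample indices); a
#'   `synthetic_record` is accepted directly.
#' @param grid A [parameter_grid()].
#' @param tolerance_ms Beat-matching window (ms).
#' @param order Butterworth order passed to the detector.
#' @param verbose Print progress per frequency band.
#' @return Data frame of class `grid_results`: one row per admissible
#'   combination with the parameter columns, `se_percent`, `pp_percent`,
#'   `overall_percent`, `tp`, `fp`, `fn`, sorted best-first. Attributes:
#'   `n_skipped`, `tolerance_ms`.
#' @examples
#' corpus <- lapply(1:2, function(s)
#'   generate_ecg(synthetic_spec(duration_s = 10, seed = s)))
#' g <- parameter_grid(f1_values = 8, f2_values = 20, w1_values = 97,
#'                     w2_values = 611, beta_values = c(0, 0.08))
#' brute_force_optimize(corpus, g)
#' @export
brute_force_optimize <- function(corpus, grid, tolerance_ms = 150,
                                 order = 3L, verbose = FALSE) {
  if (length(corpus) == 0L) stop("`corpus` is empty", call. = FALSE)
  corpus <- lapply(corpus, function(entry) {
    if (inherits(entry, "synthetic_record")) {
      list(record = entry$record, reference = entry$true_r_peaks)
    } else {
      stopifnot(is_ecg_record(entry$record), is.numeric(entry$reference))
      entry
    }
  })
  combos <- grid_combinations(grid)
  if (nrow(combos) == 0L) {
    stop("no admissible combination in the grid (need f1 < f2 and w1 < w2)",
         call. = FALSE)
  }

  bands <- unique(combos[, c("f1", "f2")])
  res <- vector("list", nrow(combos))
  row_at <- 0L
  for (b in seq_len(nrow(bands))) {
    f1 <- bands$f1[b]; f2 <- bands$f2[b]
    if (verbose) message(sprintf("band %g-%g Hz", f1, f2))
    pp <- lapply(corpus, function(entry) {
      preprocess_ecg(entry$record,
                     detector_params(f1 = f1, f2 = f2, order = order))
    })
    sub <- combos[combos$f1 == f1 & combos$f2 == f2, , drop = FALSE]
    # moving averages depend only on the window sample count per record
    ma_cache <- lapply(corpus, function(entry) new.env(parent = emptyenv()))
    ma_for <- function(i, w_samples) {
      key <- as.character(w_samples)
      env <- ma_cache[[i]]
      if (is.null(env[[key]])) {
        env[[key]] <- moving_average(pp[[i]]$squared, w_samples)
      }
      env[[key]]
    }
    for (r in seq_len(nrow(sub))) {
      w1_ms <- sub$w1_ms[r]; w2_ms <- sub$w2_ms[r]; beta <- sub$beta[r]
      tp <- fp <- fn <- 0L
      for (i in seq_along(corpus)) {
        fs <- corpus[[i]]$record$fs
        w1 <- duration_to_samples(w1_ms, fs)
        w2 <- duration_to_samples(w2_ms, fs)
        if (w1 >= w2) next
        ma <- list(ma_qrs = ma_for(i, w1), ma_beat = ma_for(i, w2),
                   w1_samples = w1, w2_samples = w2)
        alpha <- compute_offset(pp[[i]]$mean_squared, beta)
        blocks <- threshold_blocks(generate_blocks(ma, alpha), w1)
        peaks <- locate_r_peaks(blocks, pp[[i]]$filtered)
        tol <- max(0L, as.integer(round(tolerance_ms * fs / 1000)))
        m <- match_beats(peaks, corpus[[i]]$reference, tol)
        tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
      }
      sc <- score_detection(tp, fp, fn, tolerance_ms)
      row_at <- row_at + 1L
      res[[row_at]] <- data.frame(
        f1 = f1, f2 = f2, w1_ms = w1_ms, w2_ms = w2_ms, beta = beta,
        se_percent = sc$se_percent, pp_percent = sc$pp_percent,
        overall_percent = sc$overall_percent, tp = tp, fp = fp, fn = fn)
    }
  }
  out <- do.call(rbind, res[seq_len(row_at)])
  ord <- order(-out$overall_percent, -out$se_percent, out$w1_ms, out$f1,
               out$f2, out$w2_ms, out$beta)
  out <- out[ord, , drop = FALSE]
  out$combination <- seq_len(nrow(out))
  out <- out[, c("combination", setdiff(names(out), "combination"))]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- attr(combos, "n_skipped")
  attr(out, "tolerance_ms") <- tolerance_ms
  class(out) <- c("grid_results", "data.frame")
  out
}

#' Write optimizer results as CSV
#'
#' Mirrors the published training-table layout: combination rank,
#' frequency band, window sizes, offset percentage and the three scores.
#'
#' @param results A `grid_results` table from [brute_force_optimize()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_results <- function(results, path) {
  df <- data.frame(
    Combination = results$combination,
    `Frequency Band` = sprintf("%g-%g Hz", results$f1, results$f2),
    `W1 (ms)` = results$w1_ms,
    `W2 (ms)` = results$w2_ms,
    `Offset (%)` = 100 * results$beta,
    `SE (%)` = results$se_percent,
    `+P (%)` = results$pp_percent,
    `Overall Accuracy (%)` = results$overall_percent,
    check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
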