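#' Detector parameters
#'
#' The five tunable parameters of the two-moving-average QRS detector, in
#' physical units so one parameter set applies across sampling frequencies.
#' The defaults are the grid-search optimum on the MIT-BIH Arrhythmia
#' Database: passband 8-20 Hz, QRS-scale window 97 ms (35 samples at
#' 360 Hz), beat-scale window 611 ms (220 samples at 360 Hz) and offset
#' fraction 0.08.
#'
#' @param f1,f2 Passband start/stop in Hz, `0 < f1 < f2`.
#' @param w1_ms QRS-scale moving-average window in milliseconds; also the
#'   minimum accepted block width.
#' @param w2_ms Beat-scale moving-average window in milliseconds; must
#'   exceed `w1_ms`.
#' @param beta Offset fraction in `[0, 1]`: the fraction of the mean
#'   squared signal added to the beat-scale average to form the dynamic
#'   threshold.
#' @param order Butterworth filter order (default 3).
#' @param rounding Window rounding mode, `"nearest"` (default; matches the
#'   published sample counts) or `"odd"` (force odd window lengths).
#'
#' @return Object of class `detector_params` (a named list).
#' @examples
#' detector_params()
#' detector_params(f1 = 5, f2 = 15, beta = 0.05)
#' @export
detector_params <- function(f1 = 8, f2 = 20, w1_ms = 97, w2_ms = 611,
                            beta = 0.08, order = 3L,
                            rounding = c("nearest", "odd")) {
  rounding <- match.arg(rounding)
  stopifnot(is.numeric(f1), is.numeric(f2), is.numeric(w1_ms),
            is.numeric(w2_ms), is.numeric(beta))
  if (!(f1 > 0 && f1 < f2)) {
    stop("need 0 < f1 < f2", call. = FALSE)
  }
  if (!(w1_ms > 0 && w1_ms < w2_ms)) {
    stop("need 0 < w1_ms < w2_ms", call. = FALSE)
  }
  if (beta < 0 || beta > 1) {
    stop("`beta` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(f1 = f1, f2 = f2, w1_ms = w1_ms, w2_ms = w2_ms, beta = beta,
         order = as.integer(order), rounding = rounding),
    class = "detector_params"
  )
}

#' @export
print.detector_params <- function(x, ...) {
  cat(sprintf(
    "<detector_params> band %g-%g Hz, W1 %g ms, W2 %g ms, beta %g (order %d)\n",
    x$f1, x$f2, x$w1_ms, x$w2_ms, x$beta, x$order))
  invisible(x)
}

#' Convert a duration to a sample count
#'
#' Converts a physical duration (ms) to the window length in samples at a
#' given sampling frequency. `mode = "nearest"` rounds half up to the
#' nearest integer (97 ms at 360 Hz gives 35 samples, 611 ms gives 220);
#' `mode = "odd"` additionally bumps even results up by one so the moving
#' average window has a well-defined centre sample.
#'
#' @param duration_ms Duration in milliseconds (> 0).
#' @param fs Sampling frequency in Hz (> 0).
#' @param mode `"nearest"` or `"odd"`.
#' @return A positive integer sample count (minimum 1).
#' @examples
#' duration_to_samples(97, 360)    # 35
#' duration_to_samples(611, 360)   # 220
#' duration_to_samples(611, 360, mode = "odd")  # 221
#' @export
duration_to_samples <- function(duration_ms, fs, mode = c("nearest", "odd")) {
  mode <- match.arg(mode)
  if (!is.finite(duration_ms) || duration_ms <= 0) {
    stop("`duration_ms` must be positive", call. = FALSE)
  }
  if (!is.finite(fs) || fs <= 0) {
    stop("`fs` must be positive", call. = FALSE)
  }
  n <- max(1L, as.integer(floor(duration_ms * fs / 1000 + 0.5)))
  if (mode == "odd" && n %% 2L == 0L) n <- n + 1L
  n
}

#' Centred moving average
#'
#' Uniform moving average with a centred window. For odd windows the span
#' is symmetric; for an even window `w` the span is `[n - w/2, n + w/2 - 1]`
#' (left-heavy). At the edges the window shrinks to the available samples
#' and divides by the actual count, so constants are reproduced exactly
#' everywhere.
#'
#' @param x Numeric vector.
#' @param window Positive integer window length, at most `length(x)`.
#' @return Numeric vector, same length as `x`.
#' @examples
#' moving_average(rep(2, 10), 4)
#' @export
moving_average <- function(x, window) {
  n <- length(x)
  window <- as.integer(window)
  if (window < 1L) stop("`window` must be >= 1", call. = FALSE)
  if (window > n) {
    stop(sprintf("`window` (%d) exceeds signal length (%d)", window, n),
         call. = FALSE)
  }
  idx <- seq_len(n)
  lo <- pmax(idx - window %/% 2L, 1L)
  hi <- pmin(idx + (window - 1L) %/% 2L, n)
  cs <- c(0, cumsum(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Two event-related moving averages
#'
#' Computes the QRS-scale and beat-scale moving averages of the squared
#' filtered signal. The short average traces individual QRS complexes; the
#' long one tracks the per-beat energy level and serves as the dynamic
#' threshold baseline.
#'
#' @param squared Nonnegative numeric vector (squared filtered signal).
#' @param params A [detector_params()].
#' @param fs Sampling frequency in Hz.
#' @return Object of class `moving_averages`: list with `ma_qrs`,
#'   `ma_beat`, `w1_samples`, `w2_samples`.
#' @export
event_moving_averages <- function(squared, params, fs) {
  w1 <- duration_to_samples(params$w1_ms, fs, params$rounding)
  w2 <- duration_to_samples(params$w2_ms, fs, params$rounding)
  if (w1 >= w2) {
    stop("w1_ms and w2_ms round to non-increasing sample windows at this fs",
         call. = FALSE)
  }
  structure(
    list(ma_qrs = moving_average(squared, w1),
         ma_beat = moving_average(squared, w2),
         w1_samples = w1, w2_samples = w2),
    class = "moving_averages"
  )
}

#' Threshold offset from the signal mean
#'
#' The dynamic threshold is the beat-scale moving average raised by
#' `alpha = beta * mean(squared signal)`; the data-driven offset guards
#' against spurious blocks in low-SNR stretches.
#'
#' @param mean_squared Mean of the squared filtered signal (>= 0).
#' @param beta Offset fraction in `[0, 1]`.
#' @return The offset `alpha` (nonnegative scalar).
#' @examples
#' compute_offset(2.5, 0.08)  # 0.2
#' @export
compute_offset <- function(mean_squared, beta) {
  if (mean_squared < 0) stop("`mean_squared` must be >= 0", call. = FALSE)
  if (beta < 0 || beta > 1) stop("`beta` must lie in [0, 1]", call. = FALSE)
  beta * mean_squared
}

#' Generate candidate QRS blocks
#'
#' Blocks of interest are the maximal runs of samples where the QRS-scale
#' average strictly exceeds the beat-scale average plus the offset. Blocks
#' are returned in onset order, all initially unaccepted.
#'
#' @param ma A `moving_averages` object (or list with `ma_qrs`, `ma_beat`).
#' @param offset Threshold offset `alpha` (scalar).
#' @return A data frame of class `block_table` with columns `onset`
#'   (first sample, 1-based, inclusive), `end` (exclusive), `width`
#'   (samples) and `accepted` (logical). Zero rows if nothing crosses the
#'   threshold.
#' @export
generate_blocks <- function(ma, offset) {
  above <- ma$ma_qrs > ma$ma_beat + offset
  if (length(ma$ma_qrs) != length(ma$ma_beat)) {
    stop("moving-average sequences differ in length", call. = FALSE)
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  blocks <- data.frame(
    onset = starts[keep],
    end = ends[keep] + 1L,   # exclusive
    width = r$lengths[keep],
    accepted = logical(sum(keep))
  )
  class(blocks) <- c("block_table", "data.frame")
  blocks
}

#' Accept or reject blocks by width
#'
#' A block at least as wide as the QRS-scale window `W1` is classified as a
#' QRS complex (the rule is greater-than-or-equal, so blocks of average
#' healthy width and the wider arrhythmic ones are both kept); narrower
#' blocks are P/T waves or noise and stay rejected but are retained for
#' diagnostics.
#'
#' @param blocks A block table from [generate_blocks()].
#' @param w1_samples Minimum accepted width in samples (>= 1).
#' @return The block table with `accepted` filled in.
#' @export
threshold_blocks <- function(blocks, w1_samples) {
  if (w1_samples < 1L) stop("`w1_samples` must be >= 1", call. = FALSE)
  blocks$accepted <- blocks$width >= w1_samples
  blocks
}

#' Locate R peaks within accepted blocks
#'
#' The R peak of each accepted block is the sample with the maximum
#' absolute filtered amplitude inside the block; taking the absolute value
#' handles inverted QRS complexes. Ties go to the earliest sample.
#'
#' @param blocks A block table with `accepted` set.
#' @param filtered Band-pass filtered signal the blocks index into.
#' @return Strictly increasing integer vector of R-peak sample indices
#'   (1-based), one per accepted block.
#' @export
locate_r_peaks <- function(blocks, filtered) {
  acc <- blocks[blocks$accepted, , drop = FALSE]
  if (nrow(acc) == 0L) return(integer(0))
  if (any(acc$onset < 1L) || any(acc$end > length(filtered) + 1L)) {
    stop("block range outside the signal", call. = FALSE)
  }
  vapply(seq_len(nrow(acc)), function(i) {
    span <- acc$onset[i]:(acc$end[i] - 1L)
    span[which.max(abs(filtered[span]))]
  }, integer(1))
}

#' Detect QRS complexes with two event-related moving averages
#'
#' Full detection pipeline: band-pass filter, squaring, QRS- and beat-scale
#' moving averages, mean-based dynamic threshold, block generation,
#' width-based block rejection and R-peak localization. Deterministic for
#' a fixed input; invariant to positive rescaling and DC shifts of the raw
#' signal.
#'
#' @param record An [ecg_record()], or a bare numeric vector with `fs`.
#' @param params A [detector_params()].
#' @param fs Sampling frequency, only for bare-vector input.
#'
#' @return Object of class `qrs_detection`: list with `r_peaks` (1-based
#'   sample indices), `blocks` (block table), `params`, `fs`,
#'   `threshold_offset` (alpha) and window sizes `w1_samples`/`w2_samples`.
#' @examples
#' syn <- generate_ecg(synthetic_spec(duration_s = 10, seed = 1))
#' det <- detect_qrs(syn$record)
#' det$r_peaks
#' @export
detect_qrs <- function(record, params = detector_params(), fs = NULL) {
  record <- as_ecg_record(record, fs)
  min_samples <- duration_to_samples(params$w2_ms, record$fs,
                                     params$rounding)
  if (length(record$samples) < min_samples) {
    stop(sprintf(
      "record too short: %d samples < one beat-scale window (%d samples, %g ms); supply at least %.2f s of signal",
      length(record$samples), min_samples, params$w2_ms,
      min_samples / record$fs), call. = FALSE)
  }
  pp <- preprocess_ecg(record, params)
  ma <- event_moving_averages(pp$squared, params, record$fs)
  alpha <- compute_offset(pp$mean_squared, params$beta)
  blocks <- generate_blocks(ma, alpha)
  blocks <- threshold_blocks(blocks, ma$w1_samples)
  peaks <- locate_r_peaks(blocks, pp$filtered)
  structure(
    list(r_peaks = peaks, blocks = blocks, params = params, fs = record$fs,
         record_id = record$record_id, threshold_offset = alpha,
         w1_samples = ma$w1_samples, w2_samples = ma$w2_samples),
    class = "qrs_detection"
  )
}

#' @export
print.qrs_detection <- function(x, ...) {
  cat(sprintf(
    "<qrs_detection> '%s': %d R peaks (%d/%d blocks accepted) @ %g Hz\n",
    x$record_id, length(x$r_peaks), sum(x$blocks$accepted),
    nrow(x$blocks), x$fs))
  if (length(x$r_peaks) > 1L) {
    rr <- diff(x$r_peaks) / x$fs
    cat(sprintf("  mean heart rate %.1f bpm (RR %.0f +/- %.0f ms)\n",
                60 / mean(rr), 1000 * mean(rr), 1000 * stats::sd(rr)))
  }
  invisible(x)
}
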