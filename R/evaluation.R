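#' Match detected beats to reference annotations
#'
#' One-to-one greedy nearest-neighbour matching: candidate pairs within
#' `tolerance_samples` are taken in order of increasing time difference
#' (ties to the earlier detection), each detection and each reference beat
#' used at most once. Unmatched detections are false positives, unmatched
#' references false negatives.
#'
#' @param detected Strictly increasing integer vector of detected R-peak
#'   sample indices.
#' @param reference Strictly increasing integer vector of reference beat
#'   sample indices.
#' @param tolerance_samples Maximum |detected - reference| distance for a
#'   match, in samples (>= 0).
#' @return List with counts `tp`, `fp`, `fn` and a two-column matrix
#'   `pairs` (detected index, reference index) of matched positions.
#' @examples
#' match_beats(c(105, 600), c(100, 300), tolerance_samples = 10)
#' @export
match_beats <- function(detected, reference, tolerance_samples) {
  if (is.unsorted(detected, strictly = TRUE) && length(detected) > 1L) {
    stop("`detected` must be strictly increasing", call. = FALSE)
  }
  if (is.unsorted(reference, strictly = TRUE) && length(reference) > 1L) {
    stop("`reference` must be strictly increasing", call. = FALSE)
  }
  nd <- length(detected)
  nr <- length(reference)
  if (nd == 0L || nr == 0L) {
    return(list(tp = 0L, fp = nd, fn = nr,
                pairs = matrix(integer(0), ncol = 2,
                               dimnames = list(NULL, c("detected", "reference")))))
  }
  # candidate pairs within tolerance (each detection can only match
  # references within a window, so this stays near-linear in practice)
  di <- rep(seq_len(nd), each = nr)
  ri <- rep(seq_len(nr), times = nd)
  dist <- abs(detected[di] - reference[ri])
  keep <- dist <= tolerance_samples
  di <- di[keep]; ri <- ri[keep]; dist <- dist[keep]
  ord <- order(dist, di, ri)
  used_d <- logical(nd)
  used_r <- logical(nr)
  pd <- integer(0); pr <- integer(0)
  for (k in ord) {
    if (!used_d[di[k]] && !used_r[ri[k]]) {
      used_d[di[k]] <- TRUE
      used_r[ri[k]] <- TRUE
      pd <- c(pd, di[k]); pr <- c(pr, ri[k])
    }
  }
  tp <- length(pd)
  list(tp = tp, fp = nd - tp, fn = nr - tp,
       pairs = cbind(detected = detected[pd], reference = reference[pr]))
}

#' Score beat detection counts
#'
#' Sensitivity `SE = 100 * TP / (TP + FN)` is the percentage of reference
#' beats detected; positive predictivity `+P = 100 * TP / (TP + FP)` is the
#' percentage of detections that are true beats; overall accuracy is their
#' arithmetic mean. Undefined ratios (zero denominators) are reported as
#' `NA`, never as 0.
#'
#' @param tp,fp,fn Nonnegative counts.
#' @param tolerance_ms Matching tolerance recorded in the report (for
#'   provenance only).
#' @return Object of class `beat_evaluation`: list with `tp`, `fp`, `fn`,
#'   `se_percent`, `pp_percent`, `overall_percent`, `tolerance_ms`.
#' @examples
#' score_detection(tp = 99, fp = 3, fn = 1)
#' @export
score_detection <- function(tp, fp, fn, tolerance_ms = NA_real_) {
  if (tp < 0 || fp < 0 || fn < 0) stop("counts must be >= 0", call. = FALSE)
  se <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  pp <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  overall <- if (is.na(se) || is.na(pp)) NA_real_ else (se + pp) / 2
  structure(
    list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
         se_percent = se, pp_percent = pp, overall_percent = overall,
         tolerance_ms = tolerance_ms),
    class = "beat_evaluation"
  )
}

#' Evaluate detections against reference beats
#'
#' Convenience wrapper: matches beats within a millisecond tolerance and
#' scores the result.
#'
#' @param detected,reference Strictly increasing sample-index vectors.
#' @param fs Sampling frequency in Hz (converts the tolerance to samples).
#' @param tolerance_ms Matching window in ms (default 150, the conventional
#'   beat-matching window).
#' @return A `beat_evaluation` object.
#' @examples
#' syn <- generate_ecg(synthetic_spec(duration_s = 15, seed = 7))
#' det <- detect_qrs(syn$record)
#' evaluate_detection(det$r_peaks, syn$true_r_peaks, fs = syn$record$fs)
#' @export
evaluate_detection <- function(detected, reference, fs, tolerance_ms = 150) {
  tol <- max(0L, as.integer(round(tolerance_ms * fs / 1000)))
  m <- match_beats(detected, reference, tol)
  score_detection(m$tp, m$fp, m$fn, tolerance_ms = tolerance_ms)
}

#' @export
print.beat_evaluation <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat(sprintf(
    "<beat_evaluation> TP %d  FP %d  FN %d | SE %s  +P %s  overall %s",
    x$tp, x$fp, x$fn, fmt(x$se_percent), fmt(x$pp_percent),
    fmt(x$overall_percent)))
  if (!is.na(x$tolerance_ms)) cat(sprintf(" (tol %g ms)", x$tolerance_ms))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.beat_evaluation <- function(x, ...) {
  data.frame(tp = x$tp, fp = x$fp, fn = x$fn, se_percent = x$se_percent,
             pp_percent = x$pp_percent, overall_percent = x$overall_percent,
             tolerance_ms = x$tolerance_ms)
}
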