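#' Pan-Tompkins QRS detector (comparator)
#'
#' Classic adaptive-threshold QRS detector, provided as a side-by-side
#' comparator for the two-moving-average detector. Steps: resample to
#' 200 Hz (the rate its filters are designed for), subtract the mean,
#' band-pass 5-15 Hz, five-point derivative, squaring, 150 ms moving
#' integration, then dual adaptive signal/noise thresholds on the
#' integrated and filtered signals with a search-back pass for long RR
#' gaps. Detections are mapped back to the original record's sample
#' coordinates.
#'
#' The adaptive-threshold constants and the search-back rule follow the
#' canonical published description (signal/noise level updates with
#' 0.125/0.875 weights, threshold = noise + 0.25 x (signal - noise),
#' search-back at half threshold when an RR interval exceeds 166% of the
#' running average, 200 ms refractory period). The first two seconds
#' initialize the running levels.
#'
#' @param record An [ecg_record()], or bare numeric vector with `fs`.
#' @param fs Sampling frequency for bare-vector input.
#' @return Strictly increasing integer vector of R-peak indices in the
#'   original record's coordinates (1-based).
#' @examples
#' syn <- generate_ecg(synthetic_spec(duration_s = 15, seed = 2))
#' pan_tompkins_detect(syn$record)
#' @export
pan_tompkins_detect <- function(record, fs = NULL) {
  record <- as_ecg_record(record, fs)
  fs0 <- record$fs
  if (length(record$samples) / fs0 < 2) {
    stop("record shorter than 2 s; the adaptive thresholds cannot initialize",
         call. = FALSE)
  }
  x0 <- record$samples
  if (max(x0) == min(x0)) return(integer(0))  # flatline

  # resample to the 200 Hz design rate (rational polyphase)
  target <- 200
  if (fs0 == target) {
    x <- x0
  } else {
    frac <- .rational(target / fs0)
    x <- signal::resample(x0, frac[1], frac[2])
  }
  fs <- target
  x <- x - mean(x)

  bf <- signal::butter(3, c(5, 15) * 2 / fs, type = "pass")
  n <- length(x)
  pad <- min(n - 1L, fs)
  xp <- c(rev(x[seq_len(pad) + 1L]), x, rev(x[n - seq_len(pad)]))
  xf <- signal::filtfilt(bf, xp)[(pad + 1L):(pad + n)]

  # five-point derivative, squaring, 150 ms moving-window integration
  dx <- stats::filter(xf, c(1, 2, 0, -2, -1) / 8, sides = 2)
  dx[is.na(dx)] <- 0
  sq <- as.numeric(dx)^2
  wi <- max(1L, round(0.150 * fs))
  mwi <- moving_average(sq, wi)

  peaks <- .local_maxima(mwi, min_dist = round(0.2 * fs))
  if (length(peaks) == 0L) return(integer(0))

  # initialize running levels from the first 2 s
  init <- mwi[seq_len(min(n, 2L * fs))]
  spki <- 0.25 * max(init)
  npki <- 0.5 * mean(init)
  initf <- abs(xf[seq_len(min(n, 2L * fs))])
  spkf <- 0.25 * max(initf)
  npkf <- 0.5 * mean(initf)

  qrs <- integer(0)
  rr_buf <- numeric(0)
  for (p in peaks) {
    thr1 <- npki + 0.25 * (spki - npki)
    thrf1 <- npkf + 0.25 * (spkf - npkf)
    fp_amp <- max(abs(xf[max(1L, p - wi):min(n, p + wi)]))
    if (mwi[p] > thr1 && fp_amp > thrf1) {
      qrs <- c(qrs, p)
      spki <- 0.125 * mwi[p] + 0.875 * spki
      spkf <- 0.125 * fp_amp + 0.875 * spkf
      if (length(qrs) > 1L) {
        rr_buf <- c(rr_buf, diff(tail(qrs, 2)))
        if (length(rr_buf) > 8L) rr_buf <- tail(rr_buf, 8L)
      }
    } else {
      # search-back: accept at half threshold when the RR gap is long
      rr_avg <- if (length(rr_buf) > 0) mean(rr_buf) else NA_real_
      overdue <- length(qrs) > 0L && !is.na(rr_avg) &&
        (p - tail(qrs, 1)) > 1.66 * rr_avg
      if (overdue && mwi[p] > 0.5 * thr1) {
        qrs <- c(qrs, p)
        spki <- 0.25 * mwi[p] + 0.75 * spki
        spkf <- 0.25 * fp_amp + 0.75 * spkf
      } else {
        npki <- 0.125 * mwi[p] + 0.875 * npki
        npkf <- 0.125 * fp_amp + 0.875 * npkf
      }
    }
  }
  if (length(qrs) == 0L) return(integer(0))

  # fiducial: sharpest filtered deflection near each integrated peak,
  # then map back to original coordinates and snap to the local extremum
  fid <- vapply(qrs, function(p) {
    span <- max(1L, p - wi):min(n, p)
    span[which.max(abs(xf[span]))]
  }, integer(1))
  orig <- as.integer(round((fid - 1L) * fs0 / fs)) + 1L
  half <- max(1L, as.integer(round(0.025 * fs0)))
  n0 <- length(x0)
  bf0 <- signal::butter(3, c(5, min(15, fs0 / 2 * 0.99)) * 2 / fs0,
                        type = "pass")
  pad0 <- min(n0 - 1L, round(fs0))
  xp0 <- c(rev(x0[seq_len(pad0) + 1L]), x0, rev(x0[n0 - seq_len(pad0)]))
  xf0 <- signal::filtfilt(bf0, xp0)[(pad0 + 1L):(pad0 + n0)]
  snapped <- vapply(orig, function(i) {
    span <- max(1L, i - half):min(n0, i + half)
    span[which.max(abs(xf0[span]))]
  }, integer(1))
  sort(unique(snapped))
}

# local maxima at least min_dist apart, keeping the larger on conflict
.local_maxima <- function(x, min_dist) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] &
                  x[2:(n - 1L)] >= x[3:n]) + 1L
  cand <- cand[x[cand] > 0]
  if (length(cand) == 0L) return(integer(0))
  cand <- cand[order(-x[cand])]
  keep <- integer(0)
  for (p in cand) {
    if (all(abs(keep - p) >= min_dist)) keep <- c(keep, p)
  }
  sort(keep)
}

# small rational approximation p/q of a ratio (for resampling)
.rational <- function(r, max_den = 1000L) {
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(r - p / q)
    if (e < err - 1e-15) {
      err <- e; best <- c(as.integer(p), q)
      if (e < 1e-12) break
    }
  }
  best
}
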