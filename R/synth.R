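#' Specification for a synthetic ECG record
#'
#' Describes a seeded, fully reproducible synthetic single-lead ECG: a
#' periodic P-QRS-T beat train with physiological default durations
#' (P width 110 ms, PR interval 160 ms, QRS width 100 ms), optional
#' morphology variants, and the classic contamination sources — 60 Hz
#' mains with second and third harmonics, sub-1 Hz baseline wander, and
#' broadband muscle noise. Ground-truth R-peak positions are recorded
#' before noise is added, so the truth is exact by construction.
#'
#' Waves are rendered as Gaussian pulses whose nominal width spans
#' +/- 2 standard deviations; any smooth unimodal pulse exercises the
#' detector's contracts, which is what this generator is for. It does not
#' emulate real ECG micro-structure (notched QRS, ectopic morphology
#' families, electrode pops), so perfect scores here do not promise
#' database-level performance.
#'
#' @param fs Sampling frequency in Hz.
#' @param duration_s Record length in seconds.
#' @param heart_rate_bpm Heart rate in beats/minute; a single value for a
#'   fixed rate, or a length-2 vector for a linear ramp across the record.
#'   Must lie in `[20, 300]`.
#' @param qrs_width_ms,p_width_ms,t_width_ms Wave widths (+/- 2 sigma span).
#' @param pr_ms PR interval: P-wave centre precedes the R peak by this.
#' @param qrs_amp,p_amp,t_amp Wave amplitudes (mV).
#' @param inverted_qrs,widened_qrs,missing_p,biphasic_qrs Morphology flags:
#'   negate the QRS, double its width, drop P waves, or use a biphasic
#'   (derivative-of-Gaussian) QRS.
#' @param mains_60hz_amp Amplitude of 60 Hz mains interference.
#' @param mains_harmonic_amps Length-2 vector: amplitudes of the 120 and
#'   180 Hz harmonics (only rendered below Nyquist).
#' @param baseline_wander_amp,baseline_wander_hz Baseline wander amplitude
#'   and frequency (must be < 1 Hz).
#' @param muscle_noise_sd Standard deviation of white Gaussian muscle noise.
#' @param rr_jitter_sd_ms Gaussian beat-to-beat RR jitter (ms), truncated
#'   at +/- 3 sigma so beat order is preserved.
#' @param seed Integer RNG seed; same spec + same seed gives identical
#'   samples.
#' @return Object of class `synthetic_spec`.
#' @examples
#' synthetic_spec(duration_s = 10, heart_rate_bpm = 72, seed = 42)
#' @export
synthetic_spec <- function(fs = 360, duration_s = 30, heart_rate_bpm = 60,
                           qrs_width_ms = 100, p_width_ms = 110,
                           t_width_ms = 160, pr_ms = 160,
                           qrs_amp = 1, p_amp = 0.15, t_amp = 0.3,
                           inverted_qrs = FALSE, widened_qrs = FALSE,
                           missing_p = FALSE, biphasic_qrs = FALSE,
                           mains_60hz_amp = 0,
                           mains_harmonic_amps = c(0, 0),
                           baseline_wander_amp = 0,
                           baseline_wander_hz = 0.25,
                           muscle_noise_sd = 0,
                           rr_jitter_sd_ms = 0,
                           seed = 1L) {
  if (!is.finite(fs) || fs <= 0) stop("`fs` must be positive", call. = FALSE)
  if (!is.finite(duration_s) || duration_s <= 0) {
    stop("`duration_s` must be positive", call. = FALSE)
  }
  hr <- as.numeric(heart_rate_bpm)
  if (!length(hr) %in% 1:2 || any(!is.finite(hr)) ||
      any(hr < 20) || any(hr > 300)) {
    stop("`heart_rate_bpm` must be 1 or 2 finite values in [20, 300]",
         call. = FALSE)
  }
  amps <- c(qrs_amp, p_amp, t_amp, mains_60hz_amp, mains_harmonic_amps,
            baseline_wander_amp, muscle_noise_sd)
  if (any(!is.finite(amps))) {
    stop("amplitudes and noise levels must be finite", call. = FALSE)
  }
  if (length(mains_harmonic_amps) != 2L) {
    stop("`mains_harmonic_amps` must have length 2 (120 Hz, 180 Hz)",
         call. = FALSE)
  }
  if (baseline_wander_hz >= 1 || baseline_wander_hz <= 0) {
    stop("`baseline_wander_hz` must lie in (0, 1) Hz", call. = FALSE)
  }
  structure(
    list(fs = fs, duration_s = duration_s, heart_rate_bpm = hr,
         qrs_width_ms = qrs_width_ms, p_width_ms = p_width_ms,
         t_width_ms = t_width_ms, pr_ms = pr_ms,
         qrs_amp = qrs_amp, p_amp = p_amp, t_amp = t_amp,
         inverted_qrs = isTRUE(inverted_qrs),
         widened_qrs = isTRUE(widened_qrs),
         missing_p = isTRUE(missing_p),
         biphasic_qrs = isTRUE(biphasic_qrs),
         mains_60hz_amp = mains_60hz_amp,
         mains_harmonic_amps = as.numeric(mains_harmonic_amps),
         baseline_wander_amp = baseline_wander_amp,
         baseline_wander_hz = baseline_wander_hz,
         muscle_noise_sd = muscle_noise_sd,
         rr_jitter_sd_ms = rr_jitter_sd_ms,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# add a Gaussian pulse (or its derivative for biphasic QRS) in place,
# restricted to +/- 4 sigma for speed
add_pulse <- function(sig, tv, center_s, width_ms, amp, derivative = FALSE) {
  sigma <- width_ms / 1000 / 4      # nominal width spans +/- 2 sigma
  span <- which(tv >= center_s - 4 * sigma & tv <= center_s + 4 * sigma)
  if (length(span) == 0L) return(sig)
  u <- (tv[span] - center_s) / sigma
  shape <- if (derivative) -u * exp(0.5) * exp(-u^2 / 2) else exp(-u^2 / 2)
  sig[span] <- sig[span] + amp * shape
  sig
}

#' Generate a synthetic ECG record with known R peaks
#'
#' Renders the beat train described by a [synthetic_spec()], records the
#' exact ground-truth R-peak sample indices from the clean signal, then
#' adds the requested noise. Reproducible: the same spec (including seed)
#' always yields identical samples. The caller's RNG state is left
#' untouched.
#'
#' @param spec A [synthetic_spec()].
#' @return Object of class `synthetic_record`: list with `record` (an
#'   [ecg_record()]), `true_r_peaks` (1-based sample indices) and `spec`.
#' @examples
#' syn <- generate_ecg(synthetic_spec(duration_s = 10, seed = 3))
#' length(syn$true_r_peaks)
#' @export
generate_ecg <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  fs <- spec$fs
  n <- as.integer(round(spec$duration_s * fs))
  tv <- (seq_len(n) - 1L) / fs
  hr <- spec$heart_rate_bpm
  hr_at <- function(t) {
    if (length(hr) == 1L) hr else
      hr[1] + (hr[2] - hr[1]) * pmin(1, t / spec$duration_s)
  }

  # schedule beats: first R half an RR interval in, then step by the
  # instantaneous RR, with truncated Gaussian jitter
  r_times <- numeric(0)
  t <- 0.5 * 60 / hr_at(0)
  while (t < spec$duration_s) {
    jit <- 0
    if (spec$rr_jitter_sd_ms > 0) {
      jit <- stats::rnorm(1, 0, spec$rr_jitter_sd_ms / 1000)
      jit <- max(min(jit, 3 * spec$rr_jitter_sd_ms / 1000),
                 -3 * spec$rr_jitter_sd_ms / 1000)
    }
    tj <- t + jit
    if (tj >= spec$duration_s - 1 / fs) break
    r_times <- c(r_times, tj)
    t <- t + 60 / hr_at(t)
  }
  if (length(r_times) == 0L) {
    stop("record too short for a single beat at this heart rate",
         call. = FALSE)
  }
  # snap beat centres onto the sample grid so truth indices are exact
  r_idx <- pmin(n, pmax(1L, as.integer(round(r_times * fs)) + 1L))
  r_snap <- (r_idx - 1L) / fs

  qrs_w <- spec$qrs_width_ms
  qrs_a <- spec$qrs_amp * if (spec$inverted_qrs) -1 else 1
  clean <- numeric(n)
  rr_next <- c(diff(r_snap), 60 / hr_at(tail(r_snap, 1)))
  for (k in seq_along(r_snap)) {
    c_k <- r_snap[k]
    if (!spec$missing_p) {
      clean <- add_pulse(clean, tv, c_k - spec$pr_ms / 1000,
                         spec$p_width_ms, spec$p_amp)
    }
    if (spec$widened_qrs) {
      # wide QRS (e.g. bundle branch block) keeps a sharp apex on a
      # slurred base: doubled-width base under the narrow apex
      clean <- add_pulse(clean, tv, c_k, 2 * qrs_w, 0.5 * qrs_a)
    }
    clean <- add_pulse(clean, tv, c_k, qrs_w, qrs_a,
                       derivative = spec$biphasic_qrs)
    # T wave follows the R peak; its latency shortens with fast rates
    t_off <- min(0.3, 0.45 * rr_next[k])
    clean <- add_pulse(clean, tv, c_k + t_off, spec$t_width_ms, spec$t_amp)
  }

  # ground truth: largest-|amplitude| sample of the clean signal within
  # half a QRS width of each beat centre (robust to biphasic morphology)
  half_w <- max(1L, as.integer(round(qrs_w / 2 * fs / 1000)))
  true_r <- vapply(r_idx, function(i) {
    span <- max(1L, i - half_w):min(n, i + half_w)
    span[which.max(abs(clean[span]))]
  }, integer(1))
  true_r <- unique(true_r)

  sig <- clean
  if (spec$mains_60hz_amp > 0 && 60 < fs / 2) {
    sig <- sig + spec$mains_60hz_amp * sin(2 * pi * 60 * tv)
  }
  harm_f <- c(120, 180)
  for (h in 1:2) {
    if (spec$mains_harmonic_amps[h] > 0 && harm_f[h] < fs / 2) {
      sig <- sig + spec$mains_harmonic_amps[h] * sin(2 * pi * harm_f[h] * tv)
    }
  }
  if (spec$baseline_wander_amp > 0) {
    sig <- sig + spec$baseline_wander_amp *
      sin(2 * pi * spec$baseline_wander_hz * tv)
  }
  if (spec$muscle_noise_sd > 0) {
    sig <- sig + stats::rnorm(n, 0, spec$muscle_noise_sd)
  }

  structure(
    list(record = ecg_record(sig, fs, record_id = "synthetic"),
         true_r_peaks = true_r, spec = spec),
    class = "synthetic_record"
  )
}

#' @export
print.synthetic_record <- function(x, ...) {
  cat(sprintf(
    "<synthetic_record> %d beats, %.1f s @ %g Hz (seed %d)\n",
    length(x$true_r_peaks), x$spec$duration_s, x$spec$fs, x$spec$seed))
  invisible(x)
}

#' Named fixture presets for common ECG challenge conditions
#'
#' Ready-made [synthetic_spec()]s for the classic detection challenges:
#' `"clean"`, `"mains"` (60 Hz + harmonics), `"muscle"` (broadband noise),
#' `"wander"` (baseline drift), `"inverted"` and `"widened"` QRS.
#'
#' @param name Preset name.
#' @param ... Overrides forwarded to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @examples
#' fixture_preset("mains", duration_s = 10)
#' @export
fixture_preset <- function(name = c("clean", "mains", "muscle", "wander",
                                    "inverted", "widened"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    clean    = list(),
    mains    = list(mains_60hz_amp = 0.2, mains_harmonic_amps = c(0.1, 0.05)),
    muscle   = list(muscle_noise_sd = 0.1),
    wander   = list(baseline_wander_amp = 0.5, baseline_wander_hz = 0.3),
    inverted = list(inverted_qrs = TRUE),
    widened  = list(widened_qrs = TRUE)
  )
  do.call(synthetic_spec, utils::modifyList(args, list(...)))
}
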