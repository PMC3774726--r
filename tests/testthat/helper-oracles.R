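# Brute-force reference implementations, kept deliberately naive and
# independent of the package's vectorized code paths.

ma_oracle <- function(x, w) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - w %/% 2L)
    hi <- min(n, i + (w - 1L) %/% 2L)
    s <- 0
    for (j in lo:hi) s <- s + x[j]
    out[i] <- s / (hi - lo + 1L)
  }
  out
}

blocks_oracle <- function(ma_qrs, ma_beat, offset) {
  above <- ma_qrs > ma_beat + offset
  onset <- integer(0); end <- integer(0)
  inside <- FALSE
  for (i in seq_along(above)) {
    if (above[i] && !inside) { onset <- c(onset, i); inside <- TRUE }
    if (!above[i] && inside) { end <- c(end, i); inside <- FALSE }
  }
  if (inside) end <- c(end, length(above) + 1L)
  data.frame(onset = onset, end = end, width = end - onset)
}

argmax_oracle <- function(blocks, filtered) {
  out <- integer(0)
  for (i in seq_len(nrow(blocks))) {
    if (!blocks$accepted[i]) next
    best <- blocks$onset[i]; bestv <- abs(filtered[best])
    for (j in blocks$onset[i]:(blocks$end[i] - 1L)) {
      if (abs(filtered[j]) > bestv) { best <- j; bestv <- abs(filtered[j]) }
    }
    out <- c(out, best)
  }
  out
}

# closed-form magnitude response of a digital filter at frequency f (Hz)
filter_gain_at <- function(bf, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs * (seq_along(bf$b) - 1))
  za <- exp(-1i * 2 * pi * f / fs * (seq_along(bf$a) - 1))
  abs(sum(bf$b * z) / sum(bf$a * za))
}

clean_syn <- function(duration_s = 20, bpm = 60, fs = 360, seed = 1, ...) {
  generate_ecg(synthetic_spec(fs = fs, duration_s = duration_s,
                              heart_rate_bpm = bpm, seed = seed, ...))
}
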