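#' Construct a single-lead ECG record
#'
#' Bundles a uniformly sampled amplitude series with its sampling frequency.
#' All detector entry points take an `ecg_record`.
#'
#' @param samples Numeric vector of amplitudes (mV or arbitrary units).
#'   Must be non-empty and finite: missing or infinite samples are rejected
#'   rather than interpolated.
#' @param fs Sampling frequency in Hz (positive scalar).
#' @param record_id Optional text label for reports and file output.
#'
#' @return An object of class `ecg_record`: a list with elements `samples`,
#'   `fs` and `record_id`.
#' @examples
#' rec <- ecg_record(sin(2 * pi * 10 * (0:999) / 360), fs = 360)
#' rec
#' @export
ecg_record <- function(samples, fs, record_id = "ecg") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("`samples` must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("`samples` contains non-finite values (NA/NaN/Inf); ",
         "clean the signal before constructing an ecg_record", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  structure(
    list(samples = samples, fs = as.numeric(fs),
         record_id = as.character(record_id)[1L]),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> '%s': %d samples @ %g Hz (%.1f s)\n",
              x$record_id, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$samples)

is_ecg_record <- function(x) inherits(x, "ecg_record")

as_ecg_record <- function(x, fs = NULL) {
  if (is_ecg_record(x)) return(x)
  if (is.null(fs)) stop("`fs` required when passing a bare numeric signal",
                        call. = FALSE)
  ecg_record(x, fs)
}
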