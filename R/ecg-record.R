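#' Construct a single-channel ECG record
#'
#' An `ecg_record` holds a uniformly sampled single-channel waveform in
#' physical units (mV) together with its sampling frequency and identifier.
#' It is the carrier object consumed by every detector and by the noise
#' mixer.
#'
#' @param samples Numeric vector of amplitudes in mV. Must be non-empty and
#'   free of non-finite values.
#' @param fs Sampling frequency in Hz (positive scalar). MIT-BIH Arrhythmia
#'   Database records use 360 Hz.
#' @param record_id Character identifier, e.g. `"100"`.
#' @param channel_index Zero-based index of the channel this waveform was
#'   taken from (metadata only).
#' @param units Unit string, `"mV"` by default.
#' @param gain ADC gain in ADC units per physical unit, used when the record
#'   is written back to disk. Default 200 (the MIT-BIH convention).
#' @param baseline ADC value corresponding to 0 physical units.
#'
#' @return An object of class `ecg_record`.
#' @examples
#' rec <- ecg_record(sin(2 * pi * 5 * seq(0, 1, by = 1 / 360)), fs = 360)
#' rec
#' @export
ecg_record <- function(samples, fs, record_id = "synthetic", channel_index = 0L,
                       units = "mV", gain = 200, baseline = 0L) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz).", call. = FALSE)
  }
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop("`samples` must be a non-empty numeric vector.", call. = FALSE)
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("`samples` must not contain NA or non-finite values.", call. = FALSE)
  }
  if (!is.numeric(gain) || length(gain) != 1L || gain <= 0) {
    stop("`gain` must be a single positive number.", call. = FALSE)
  }
  structure(
    list(
      record_id = as.character(record_id),
      fs = as.numeric(fs),
      samples = as.numeric(samples),
      channel_index = as.integer(channel_index),
      units = units,
      gain = as.numeric(gain),
      baseline = as.integer(baseline)
    ),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf(
    "<ecg_record '%s'>  %d samples @ %g Hz (%.2f s), channel %d, %s\n",
    x$record_id, length(x$samples), x$fs, length(x$samples) / x$fs,
    x$channel_index, x$units
  ))
  invisible(x)
}

#' @rdname ecg_record
#' @param x Object to test.
#' @export
is_ecg_record <- function(x) inherits(x, "ecg_record")

#' Duration of a record in seconds
#' @param record An [ecg_record()].
#' @return Scalar duration in seconds.
#' @export
record_duration <- function(record) {
  stopifnot(is_ecg_record(record))
  length(record$samples) / record$fs
}
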