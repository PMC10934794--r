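# Shared detector machinery: moving averages with exact partial-window
# edges, detection-result construction, refractory validation.

# Causal moving average: mean of the last `n` samples (partial means at the
# start so the output has no NA edge).
ma_causal <- function(x, n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  cs <- cumsum(x)
  N <- length(x)
  out <- numeric(N)
  head_n <- seq_len(min(n - 1L, N))
  out[head_n] <- cs[head_n] / head_n
  if (N >= n) {
    idx <- n:N
    out[idx] <- (cs[idx] - c(0, cs)[idx - n + 1L]) / n
  }
  out
}

# Centered moving average over a window of `n` samples (window split
# floor/ceil around the current sample; exact partial means at both edges).
ma_centered <- function(x, n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  N <- length(x)
  h1 <- (n - 1L) %/% 2L
  h2 <- n - 1L - h1
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(N) - h1, 1L)
  hi <- pmin(seq_len(N) + h2, N)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

ms_to_samples <- function(ms, fs) as.integer(round(ms * fs / 1000))

#' Construct a detections table
#'
#' Detections are a tibble with columns `record_id`, `algorithm` and
#' `sample` (0-based detected R-peak sample indices, strictly increasing).
#' Construction validates the refractory invariant: consecutive detections
#' must be separated by at least the refractory period.
#'
#' @param record The [ecg_record()] the detections refer to.
#' @param algorithm Integer algorithm id (1-4).
#' @param sample Integer vector of 0-based sample indices, strictly
#'   increasing.
#' @param params The parameter list used for the run (stored as an
#'   attribute).
#' @param refractory_ms Refractory period used for validation, in ms.
#' @return A tibble of class `qrs_detections`.
#' @export
qrs_detections <- function(record, algorithm, sample, params = list(),
                           refractory_ms = 200) {
  sample <- as.integer(sample)
  if (length(sample) > 1L) {
    gaps <- diff(sample)
    if (any(gaps <= 0L)) {
      stop("detections must be strictly increasing.", call. = FALSE)
    }
    refr <- ms_to_samples(refractory_ms, record$fs)
    if (any(gaps < refr)) {
      stop("detections violate the ", refractory_ms, " ms refractory period.",
        call. = FALSE
      )
    }
  }
  out <- tibble::tibble(
    record_id = record$record_id,
    algorithm = as.integer(algorithm),
    sample = sample
  )
  attr(out, "params") <- params
  attr(out, "fs") <- record$fs
  class(out) <- c("qrs_detections", class(out))
  out
}

#' Run one of the four QRS detectors
#'
#' Thin dispatcher over [detect_alg1()], [detect_alg2()], [detect_alg3()]
#' and [detect_alg4()].
#'
#' @param record An [ecg_record()].
#' @param algorithm Integer 1-4.
#' @param params Optional parameter list from the matching `algN_params()`
#'   constructor; defaults are used when `NULL`.
#' @return A [qrs_detections()] tibble.
#' @export
detect_qrs <- function(record, algorithm, params = NULL) {
  algorithm <- as.integer(algorithm)
  switch(as.character(algorithm),
    "1" = detect_alg1(record, params %||% alg1_params()),
    "2" = detect_alg2(record, params %||% alg2_params()),
    "3" = detect_alg3(record, params %||% alg3_params()),
    "4" = detect_alg4(record, params %||% alg4_params()),
    stop("`algorithm` must be 1, 2, 3 or 4.", call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_record_length <- function(record, min_samples, what) {
  stopifnot(is_ecg_record(record))
  if (length(record$samples) < min_samples) {
    stop(what, " requires at least ", min_samples, " samples (got ",
      length(record$samples), ").",
      call. = FALSE
    )
  }
}
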