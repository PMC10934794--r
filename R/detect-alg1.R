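#' Parameters for Algorithm 1
#'
#' Algorithm 1 is a low-power detector built from a
#' differentiate / moving-window-average / square preprocessing chain and a
#' three-state thresholding machine with an exponentially decaying
#' threshold. The 260 ms search window and 200 ms wait state are part of
#' the algorithm's definition; the moving-average window, decay time
#' constant, threshold coefficient and learning period are implementation
#' parameters exposed here.
#'
#' @param mwa_window_ms Moving-window-average length in ms applied to the
#'   first difference. Default 36 ms — the QRS rise-time scale. With a
#'   causal window the feature approximates `(x(t) - x(t-W))^2`, whose
#'   two lobes sit near `W/2 -/+ sigma` of the R apex (`sigma` the QRS
#'   half-width), so a window on the rise-time scale keeps the feature
#'   argmax within about 15 samples of the apex even for wide ventricular
#'   complexes.
#' @param search_window_ms Fixed State-1 maximum-search window (260 ms).
#' @param refractory_ms State-2 wait after a detection (200 ms).
#' @param decay_tau_ms Time constant of the exponential threshold decay in
#'   State 3.
#' @param threshold_coeff Coefficient `c` applied to the running mean of
#'   feature amplitudes at previously found R-peaks to seed the decaying
#'   threshold.
#' @param learning_period_s Initial span used to seed the first threshold
#'   from the feature maximum.
#' @return A parameter list of class `alg1_params`.
#' @export
alg1_params <- function(mwa_window_ms = 36, search_window_ms = 260,
                        refractory_ms = 200, decay_tau_ms = 200,
                        threshold_coeff = 0.5, learning_period_s = 2) {
  stopifnot(
    mwa_window_ms > 0, search_window_ms > 0, refractory_ms > 0,
    decay_tau_ms > 0, threshold_coeff > 0, learning_period_s > 0
  )
  structure(
    list(
      mwa_window_ms = mwa_window_ms, search_window_ms = search_window_ms,
      refractory_ms = refractory_ms, decay_tau_ms = decay_tau_ms,
      threshold_coeff = threshold_coeff, learning_period_s = learning_period_s
    ),
    class = c("alg1_params", "list")
  )
}

#' Detect R-peaks with Algorithm 1 (decaying-threshold detector)
#'
#' Feature signal: `square(MWA(first difference(x)))`, computed exactly in
#' that order. The decision machine cycles through three states: State 1
#' marks the R-peak at the feature argmax within a 260 ms window opened
#' when the decaying threshold is crossed; State 2 waits 200 ms; State 3
#' decays the threshold exponentially from `c *` (mean feature amplitude at
#' all prior R-peaks) until the feature exceeds it. The first threshold is
#' seeded from the feature maximum over the learning period; the machine
#' nevertheless scans from the first sample, so beats inside the learning
#' span are detectable.
#'
#' @param record An [ecg_record()].
#' @param params An [alg1_params()] list.
#' @return A [qrs_detections()] tibble (0-based sample indices).
#' @export
detect_alg1 <- function(record, params = alg1_params()) {
  fs <- record$fs
  check_record_length(
    record, max(2L, ms_to_samples(1000 * params$learning_period_s, fs)),
    "Algorithm 1"
  )
  x <- record$samples
  n <- length(x)
  d <- c(diff(x), 0)
  feat <- ma_causal(d, max(1L, ms_to_samples(params$mwa_window_ms, fs)))^2

  win <- max(1L, ms_to_samples(params$search_window_ms, fs))
  refr <- max(1L, ms_to_samples(params$refractory_ms, fs))
  tau <- params$decay_tau_ms * fs / 1000
  learn_n <- min(n, ms_to_samples(1000 * params$learning_period_s, fs))

  thr_start <- params$threshold_coeff * max(feat[seq_len(learn_n)])
  decay_from <- 1L
  peak_amps <- numeric(0)
  peaks <- integer(0)

  i <- 1L
  while (i <= n) {
    thr <- thr_start * exp(-(i - decay_from) / tau)
    if (feat[i] > thr && thr_start > 0) {
      hi <- min(n, i + win - 1L)
      r <- i - 1L + which.max(feat[i:hi])
      peaks <- c(peaks, r)
      peak_amps <- c(peak_amps, feat[r])
      i <- r + refr # State 2: 200 ms wait
      thr_start <- params$threshold_coeff * mean(peak_amps)
      decay_from <- i
    } else {
      i <- i + 1L
    }
  }
  qrs_detections(record, 1L, peaks - 1L, params,
    refractory_ms = params$refractory_ms
  )
}
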