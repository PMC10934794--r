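#' Parameters for Algorithm 2
#'
#' Algorithm 2 runs two parallel high-pass paths, each realized as the
#' signal minus a moving average followed by rectification. The short
#' window path `u[n]` (higher cutoff) triggers the 200 ms search window;
#' the long-window path `y[n]` (lower cutoff) is searched for its maximum,
#' which becomes the R-peak. The trigger threshold is a convex combination
#' of its previous value and the last R-peak amplitude on `y`.
#'
#' @param n_short Short moving-average window in samples (default 28,
#'   about 78 ms at 360 Hz).
#' @param n_long Long moving-average window in samples (default 110, about
#'   306 ms at 360 Hz). Must exceed `n_short`.
#' @param search_window_ms Fixed search window length (200 ms).
#' @param refractory_ms Waiting state after an R-peak (200 ms).
#' @param alpha Weight of the previous threshold in the update (0.7).
#' @param beta Weight of the last R-peak contribution (0.3); `alpha +
#'   beta` must equal 1.
#' @param threshold_fraction Fraction of the last R-peak amplitude fed
#'   into the threshold update (0.4). The threshold is compared against
#'   the short-window path `u`, whose QRS excursions are necessarily
#'   smaller than the R amplitude read off the long-window path `y` — for
#'   wide ventricular or paced complexes roughly half of it; a convex
#'   combination converging to the full R amplitude would rise above
#'   every `u` excursion and stall the detector, so the update tracks a
#'   fraction low enough that wide-complex excursions still cross.
#' @param init_coeff Fraction of the maximum of `u` over the first
#'   `init_period_s` seconds used to seed the threshold.
#' @param init_period_s Length of the threshold initialization span.
#' @return A parameter list of class `alg2_params`.
#' @export
alg2_params <- function(n_short = 28L, n_long = 110L, search_window_ms = 200,
                        refractory_ms = 200, alpha = 0.7, beta = 0.3,
                        threshold_fraction = 0.4, init_coeff = 0.5,
                        init_period_s = 2) {
  stopifnot(
    n_short >= 1L, n_long > n_short, search_window_ms > 0,
    refractory_ms > 0, alpha >= 0, beta >= 0, threshold_fraction > 0,
    init_coeff > 0, init_period_s > 0
  )
  if (abs(alpha + beta - 1) > 1e-9) {
    stop("`alpha` + `beta` must equal 1.", call. = FALSE)
  }
  structure(
    list(
      n_short = as.integer(n_short), n_long = as.integer(n_long),
      search_window_ms = search_window_ms, refractory_ms = refractory_ms,
      alpha = alpha, beta = beta, threshold_fraction = threshold_fraction,
      init_coeff = init_coeff, init_period_s = init_period_s
    ),
    class = c("alg2_params", "list")
  )
}

#' Detect R-peaks with Algorithm 2 (dual moving-average detector)
#'
#' `u[n] = |x[n] - MA_short(x)[n]|` opens a 200 ms search window when it
#' crosses the adaptive threshold (State 1); the R-peak is the argmax of
#' `y[n] = |x[n] - MA_long(x)[n]|` within the window (State 2); State 3
#' waits out the refractory period and updates
#' `threshold <- alpha * threshold + beta * y[R]`. Because every stage is
#' homogeneous of degree one in the input, scaling the signal leaves the
#' detection positions unchanged.
#'
#' @param record An [ecg_record()].
#' @param params An [alg2_params()] list.
#' @return A [qrs_detections()] tibble (0-based sample indices).
#' @export
detect_alg2 <- function(record, params = alg2_params()) {
  fs <- record$fs
  check_record_length(record, params$n_long + 1L, "Algorithm 2")
  x <- record$samples
  n <- length(x)
  u <- abs(x - ma_centered(x, params$n_short))
  y <- abs(x - ma_centered(x, params$n_long))

  win <- max(1L, ms_to_samples(params$search_window_ms, fs))
  refr <- max(1L, ms_to_samples(params$refractory_ms, fs))
  init_n <- min(n, ms_to_samples(1000 * params$init_period_s, fs))
  thr <- params$init_coeff * max(u[seq_len(init_n)])

  peaks <- integer(0)
  i <- 1L
  while (i <= n) {
    if (u[i] > thr && thr > 0) {
      hi <- min(n, i + win - 1L)
      r <- i - 1L + which.max(y[i:hi])
      peaks <- c(peaks, r)
      thr <- params$alpha * thr +
        params$beta * params$threshold_fraction * y[r]
      i <- r + refr # State 3: waiting state
    } else {
      i <- i + 1L
    }
  }
  qrs_detections(record, 2L, peaks - 1L, params,
    refractory_ms = params$refractory_ms
  )
}
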