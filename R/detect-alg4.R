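#' Parameters for Algorithm 4 (Pan-Tompkins style detector)
#'
#' The classic preprocessing chain — band-pass filter, differentiation,
#' squaring, moving-window integration — with a Butterworth band-pass in
#' place of the original cascaded integer filters, followed by a simplified
#' decision stage: the first local maximum of the integrated feature above
#' the detection threshold is the R-peak, sub-threshold maxima update the
#' noise estimate, thresholds adapt with the classic 0.125/0.875 weights, a
#' searchback with half threshold fires when no beat is found within 1.66
#' average RR intervals, and the threshold is halved when the rhythm turns
#' irregular (an RR outside 92-116% of the running average). The parallel
#' second threshold on the band-passed signal is not applied.
#'
#' @param order Butterworth section order (default 2).
#' @param low_hz,high_hz Band-pass corner frequencies (5 and 15 Hz).
#' @param integration_window_ms Moving-window-integration length (150 ms).
#' @param refractory_ms Post-detection wait (200 ms).
#' @param signal_weight Weight of a new signal peak in the SPK update
#'   (0.125; searchback detections use twice that).
#' @param noise_weight Weight of a new noise peak in the NPK update
#'   (0.125).
#' @param threshold_fraction Position of the detection threshold between
#'   NPK and SPK (0.25).
#' @param searchback_factor Multiple of the average RR after which
#'   searchback with half threshold is performed (1.66).
#' @param rr_window Number of most recent RR intervals averaged (8).
#' @param rr_low,rr_high Regularity band as fractions of the average RR
#'   (0.92 and 1.16).
#' @param learning_period_s Span used to seed SPK/NPK.
#' @return A parameter list of class `alg4_params`.
#' @export
alg4_params <- function(order = 2L, low_hz = 5, high_hz = 15,
                        integration_window_ms = 150, refractory_ms = 200,
                        signal_weight = 0.125, noise_weight = 0.125,
                        threshold_fraction = 0.25, searchback_factor = 1.66,
                        rr_window = 8L, rr_low = 0.92, rr_high = 1.16,
                        learning_period_s = 2) {
  stopifnot(
    order >= 1L, low_hz > 0, high_hz > low_hz,
    integration_window_ms > 0, refractory_ms > 0,
    signal_weight > 0, signal_weight < 1, noise_weight > 0, noise_weight < 1,
    threshold_fraction > 0, threshold_fraction < 1, searchback_factor > 1,
    rr_window >= 1L, rr_low < 1, rr_high > 1, learning_period_s > 0
  )
  structure(
    list(
      order = as.integer(order), low_hz = low_hz, high_hz = high_hz,
      integration_window_ms = integration_window_ms,
      refractory_ms = refractory_ms, signal_weight = signal_weight,
      noise_weight = noise_weight, threshold_fraction = threshold_fraction,
      searchback_factor = searchback_factor, rr_window = as.integer(rr_window),
      rr_low = rr_low, rr_high = rr_high,
      learning_period_s = learning_period_s
    ),
    class = c("alg4_params", "list")
  )
}

# Preprocessing chain: zero-phase Butterworth band-pass, five-point
# derivative, squaring, moving-window integration. Exposed internally so
# tests can probe the feature stage.
alg4_feature <- function(record, params = alg4_params()) {
  fs <- record$fs
  if (params$high_hz >= fs / 2) {
    stop("band-pass upper corner must lie below the Nyquist frequency.",
      call. = FALSE
    )
  }
  bf <- signal::butter(params$order, c(params$low_hz, params$high_hz) / (fs / 2),
    type = "pass"
  )
  bp <- signal::filtfilt(bf, record$samples)
  der <- stats::filter(bp, c(1, 2, 0, -2, -1) / 8, sides = 2)
  der[is.na(der)] <- 0
  ma_centered(as.numeric(der)^2, max(1L, ms_to_samples(params$integration_window_ms, fs)))
}

#' Detect R-peaks with Algorithm 4 (Pan-Tompkins style)
#'
#' @param record An [ecg_record()].
#' @param params An [alg4_params()] list.
#' @return A [qrs_detections()] tibble (0-based sample indices).
#' @seealso [alg4_params()] for the decision-stage description.
#' @export
detect_alg4 <- function(record, params = alg4_params()) {
  fs <- record$fs
  check_record_length(
    record,
    max(
      3L * (2L * params$order + 1L) * 3L, # filtfilt transient guard
      ms_to_samples(1000 * params$learning_period_s, fs)
    ),
    "Algorithm 4"
  )
  feat <- alg4_feature(record, params)
  n <- length(feat)
  refr <- max(1L, ms_to_samples(params$refractory_ms, fs))

  # Candidate peaks: strict local maxima that are also dominant over the
  # refractory span. Under measurement noise every ripple is a strict
  # local maximum, so the threshold logic operates on maxima that are the
  # largest feature value within +/- one refractory period — the usual
  # peak-candidate rule in Pan-Tompkins style implementations.
  is_peak <- c(FALSE, feat[2:(n - 1)] > feat[1:(n - 2)] &
    feat[2:(n - 1)] > feat[3:n], FALSE)
  pk_idx <- which(is_peak)
  dominant <- vapply(pk_idx, function(i) {
    lo <- max(1L, i - refr)
    hi <- min(n, i + refr)
    feat[i] >= max(feat[lo:hi])
  }, logical(1))
  pk_idx <- pk_idx[dominant]
  pk_val <- feat[pk_idx]

  learn_n <- min(n, ms_to_samples(1000 * params$learning_period_s, fs))
  spk <- max(feat[seq_len(learn_n)])
  npk <- mean(feat[seq_len(learn_n)]) / 2
  t1 <- npk + params$threshold_fraction * (spk - npk)

  qrs <- integer(0)
  rr_hist <- numeric(0)
  last_qrs <- NA_integer_
  cand_idx <- integer(0) # sub-threshold/skipped peaks since the last beat
  cand_val <- numeric(0)

  for (p in seq_along(pk_idx)) {
    s <- pk_idx[[p]]
    v <- pk_val[[p]]

    # searchback: no beat within searchback_factor * average RR
    if (!is.na(last_qrs) && length(rr_hist) > 0L) {
      rr_avg <- mean(utils::tail(rr_hist, params$rr_window))
      if (s - last_qrs > params$searchback_factor * rr_avg &&
        length(cand_idx) > 0L) {
        ok <- cand_val > t1 / 2 & (cand_idx - last_qrs) >= refr
        if (any(ok)) {
          b <- which(ok)[which.max(cand_val[ok])]
          sb_s <- cand_idx[[b]]
          sb_v <- cand_val[[b]]
          if (s - sb_s >= refr) {
            qrs <- c(qrs, sb_s)
            rr_hist <- c(rr_hist, sb_s - last_qrs)
            last_qrs <- sb_s
            spk <- 2 * params$signal_weight * sb_v +
              (1 - 2 * params$signal_weight) * spk
            t1 <- npk + params$threshold_fraction * (spk - npk)
            cand_idx <- integer(0)
            cand_val <- numeric(0)
          }
        }
      }
    }

    if (!is.na(last_qrs) && s - last_qrs < refr) next # State 2 wait

    if (v > t1) {
      if (!is.na(last_qrs)) {
        rr <- s - last_qrs
        rr_avg <- if (length(rr_hist)) mean(utils::tail(rr_hist, params$rr_window)) else rr
        if (rr < params$rr_low * rr_avg || rr > params$rr_high * rr_avg) {
          t1 <- t1 / 2 # irregular rhythm: halve the threshold
        }
        rr_hist <- c(rr_hist, rr)
      }
      qrs <- c(qrs, s)
      last_qrs <- s
      spk <- params$signal_weight * v + (1 - params$signal_weight) * spk
      cand_idx <- integer(0)
      cand_val <- numeric(0)
    } else {
      npk <- params$noise_weight * v + (1 - params$noise_weight) * npk
      cand_idx <- c(cand_idx, s)
      cand_val <- c(cand_val, v)
    }
    t1 <- npk + params$threshold_fraction * (spk - npk)
  }

  qrs_detections(record, 4L, sort(qrs) - 1L, params,
    refractory_ms = params$refractory_ms
  )
}
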