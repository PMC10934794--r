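#' Parameters for Algorithm 3
#'
#' Algorithm 3 simulates a level-crossing analog-to-digital converter
#' (LC-ADC) with asymmetric hysteresis, followed by a peak detector and a
#' beat detector. The input range is divided into `2^M - 1` uniformly
#' spaced levels; a sample (event) is emitted when the signal crosses a
#' level in the same direction as the previous event, or when it has
#' crossed `k_l` levels in the opposite direction. The beat detector
#' declares an R-peak at a direction-reversal event whose preceding
#' monotonic run crosses at least `l_min` levels within its final
#' `d_max_ms` — a slope criterion: only the QRS traverses a large part of
#' the amplitude range that fast.
#'
#' @param resolution_bits Sampling resolution `M`; the amplitude range is
#'   divided into `2^M - 1` levels. Default 8.
#' @param k_l Hysteresis: number of opposite-direction level crossings
#'   required before a reversal event is emitted. Default 4.
#' @param l_min Minimum number of level crossings inside the qualifying
#'   window for a reversal to count as a beat. Default 64 — a quarter of
#'   the input range at the default resolution. A QRS upstroke traverses
#'   well over half the range within tens of ms; T waves cross at most
#'   about a sixth of it within the window.
#' @param d_max_ms Length of the qualifying window ending at the reversal
#'   event; only run crossings inside it are counted. Default 120, a QRS
#'   duration.
#' @param refractory_ms Refractory period (200 ms).
#' @param timer_bits Width of the inter-event interval counter; the
#'   `dt11` field of the event stream is the interval modulo
#'   `2^timer_bits` ticks. Default 11.
#' @return A parameter list of class `alg3_params`.
#' @export
alg3_params <- function(resolution_bits = 8L, k_l = 4L, l_min = 64L,
                        d_max_ms = 120, refractory_ms = 200,
                        timer_bits = 11L) {
  stopifnot(
    resolution_bits >= 2L, k_l >= 1L, l_min >= 1L, d_max_ms > 0,
    refractory_ms > 0, timer_bits >= 1L
  )
  structure(
    list(
      resolution_bits = as.integer(resolution_bits), k_l = as.integer(k_l),
      l_min = as.integer(l_min), d_max_ms = d_max_ms,
      refractory_ms = refractory_ms, timer_bits = as.integer(timer_bits)
    ),
    class = c("alg3_params", "list")
  )
}

#' Simulate level-crossing sampling of a record
#'
#' Emits the LC-ADC event stream for a uniformly sampled input. Levels are
#' `2^M - 1` values uniformly spanning the record's amplitude range; a
#' sample lying exactly on a level counts as a crossing in the direction of
#' motion. The `dv` field is a two-bit direction code: `"01"` for an
#' upward continuation, `"10"` for a downward continuation, and `"11"` /
#' `"00"` for hysteresis reversal events at a local maximum / minimum —
#' the codes the peak detector flags.
#'
#' @param record An [ecg_record()] with a non-degenerate amplitude range.
#' @param params An [alg3_params()] list.
#' @return A tibble with one row per event: `level` (level index),
#'   `direction` (1 up / 0 down), `token` (always 1), `dt11` (inter-event
#'   interval in sampling ticks modulo `2^timer_bits`), `sample` (0-based
#'   absolute sample index, retained for evaluation), `dv`.
#' @export
lc_adc_sample <- function(record, params = alg3_params()) {
  stopifnot(is_ecg_record(record))
  x <- record$samples
  rng <- range(x)
  empty <- tibble::tibble(
    level = integer(), direction = integer(), token = integer(),
    dt11 = integer(), sample = integer(), dv = character()
  )
  if (diff(rng) == 0) {
    return(empty) # constant signal never crosses a level
  }
  n_levels <- 2L^params$resolution_bits - 1L
  levels <- seq(rng[1L], rng[2L], length.out = n_levels)
  # integer level position of each sample: number of levels at or below it
  pos <- findInterval(x, levels)

  ev_level <- integer(0)
  ev_dir <- integer(0)
  ev_sample <- integer(0)
  ev_rev <- logical(0)

  last_dir <- NA_integer_
  anchor <- pos[1L] # level index of the last emitted event (or start)
  for (i in 2L:length(x)) {
    if (pos[i] == pos[i - 1L]) next
    dir <- if (pos[i] > pos[i - 1L]) 1L else 0L
    crossed <- if (dir == 1L) {
      (pos[i - 1L] + 1L):pos[i]
    } else {
      pos[i - 1L]:(pos[i] + 1L)
    }
    for (lev in crossed) {
      if (is.na(last_dir) || dir == last_dir) {
        emit <- TRUE
        rev <- FALSE
      } else {
        # opposite direction: require k_l levels of travel from the anchor
        emit <- abs(lev - anchor) >= params$k_l
        rev <- emit
      }
      if (emit) {
        ev_level <- c(ev_level, lev)
        ev_dir <- c(ev_dir, dir)
        ev_sample <- c(ev_sample, i)
        ev_rev <- c(ev_rev, rev)
        last_dir <- dir
        anchor <- lev
      }
    }
  }
  if (length(ev_level) == 0L) {
    return(empty)
  }
  dv <- ifelse(ev_rev, ifelse(ev_dir == 1L, "00", "11"),
    ifelse(ev_dir == 1L, "01", "10")
  )
  wrap <- 2L^params$timer_bits
  dt <- diff(c(ev_sample[1L], ev_sample)) %% wrap
  tibble::tibble(
    level = ev_level, direction = ev_dir, token = 1L,
    dt11 = as.integer(dt), sample = ev_sample - 1L, dv = dv
  )
}

#' Detect R-peaks with Algorithm 3 (level-crossing detector)
#'
#' Runs [lc_adc_sample()], flags reversal events (`dv` of `"00"` or
#' `"11"`: the converter took a sample after crossing `k_l` levels against
#' the previous direction, i.e. just past a local extremum), and declares
#' an R-peak at a flagged event preceded by at least `l_min` monotonic
#' level crossings within the final `d_max_ms`, subject to the refractory
#' period. The reported position is the flagged event's absolute sample.
#'
#' @param record An [ecg_record()].
#' @param params An [alg3_params()] list.
#' @return A [qrs_detections()] tibble (0-based sample indices).
#' @export
detect_alg3 <- function(record, params = alg3_params()) {
  check_record_length(record, 2L, "Algorithm 3")
  ev <- lc_adc_sample(record, params)
  fs <- record$fs
  refr <- max(1L, ms_to_samples(params$refractory_ms, fs))
  peaks <- integer(0)
  if (nrow(ev) > 0L) {
    run_start_idx <- 1L # first event of the current monotonic run
    last_peak <- -Inf
    for (j in seq_len(nrow(ev))) {
      if (ev$dv[j] %in% c("00", "11")) {
        # crossings of the preceding monotonic run inside the qualifying
        # window ending at this reversal event
        d_max_smp <- params$d_max_ms * fs / 1000
        run_idx <- seq_len(j - 1L)
        run_idx <- run_idx[run_idx >= run_start_idx]
        span <- sum(ev$sample[j] - ev$sample[run_idx] <= d_max_smp)
        if (span >= params$l_min &&
          ev$sample[j] - last_peak >= refr) {
          peaks <- c(peaks, ev$sample[j])
          last_peak <- ev$sample[j]
        }
        run_start_idx <- j # the reversal starts the new run
      }
    }
  }
  qrs_detections(record, 3L, peaks, params,
    refractory_ms = params$refractory_ms
  )
}
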