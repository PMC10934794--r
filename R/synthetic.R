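#' Specification for a synthetic ECG record
#'
#' Beats are sums of smooth Gaussian bumps (P wave, QRS complex, T wave)
#' placed at RR-jittered positions, so the R apex sample of every beat is
#' analytically known and becomes the ground-truth annotation. Morphology
#' controls polarity, width and amplitude: V-type beats are wide and large
#' with no preceding P wave and an inverted T wave; paced (P-type) beats
#' are a narrow stimulus spike followed by a wide complex; L/R bundle
#' branch block beats are widened and asymmetric.
#'
#' @param fs Sampling frequency in Hz (default 360, the MIT-BIH rate).
#' @param duration_s Record duration in seconds.
#' @param heart_rate_bpm Mean heart rate; ignored when `rr_s` is given.
#' @param rr_s Optional explicit RR-interval sequence in seconds.
#' @param morphology Character vector recycled over beats, drawn from
#'   `c("N","L","R","V","P","A")`.
#' @param rr_jitter_fraction Uniform jitter applied to each RR interval as
#'   a fraction of the nominal RR (default 0.05).
#' @param baseline_amp_mv,baseline_freq_hz Sinusoidal baseline wander
#'   (default 0.05 mV at 0.3 Hz).
#' @param noise_mv Standard deviation of additive white measurement noise
#'   (default 0.005 mV, a realistic quantization/sensor floor).
#' @param seed Integer seed; identical seeds give bitwise-identical
#'   records.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(fs = 360, duration_s = 30, heart_rate_bpm = 60,
                       rr_s = NULL, morphology = "N",
                       rr_jitter_fraction = 0.05,
                       baseline_amp_mv = 0.05, baseline_freq_hz = 0.3,
                       noise_mv = 0.005, seed = 1L) {
  stopifnot(
    fs > 0, duration_s > 0, heart_rate_bpm > 0,
    rr_jitter_fraction >= 0, baseline_amp_mv >= 0, noise_mv >= 0
  )
  bad <- setdiff(morphology, setdiff(morphology_levels, "OTHER"))
  if (length(bad)) {
    stop("unsupported morphology label(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      fs = fs, duration_s = duration_s, heart_rate_bpm = heart_rate_bpm,
      rr_s = rr_s, morphology = morphology,
      rr_jitter_fraction = rr_jitter_fraction,
      baseline_amp_mv = baseline_amp_mv, baseline_freq_hz = baseline_freq_hz,
      noise_mv = noise_mv, seed = as.integer(seed)
    ),
    class = c("synth_spec", "list")
  )
}

# Per-morphology beat templates: list of bumps (amp mV, center offset s
# relative to the R apex, sd s). The R bump must dominate so the apex is
# the within-beat argmax.
beat_template <- function(morphology) {
  switch(morphology,
    N = list(
      p = c(0.15, -0.17, 0.020), q = c(-0.10, -0.023, 0.006),
      r = c(1.00, 0.000, 0.009), s = c(-0.20, 0.025, 0.007),
      t = c(0.30, 0.22, 0.045)
    ),
    L = list( # wide, slurred complex
      p = c(0.12, -0.17, 0.020), r = c(1.00, 0.000, 0.016),
      s = c(-0.35, 0.045, 0.014), t = c(0.25, 0.24, 0.050)
    ),
    R = list( # rsR'-like: secondary positive wave after the main one
      p = c(0.12, -0.17, 0.020), q = c(-0.15, -0.025, 0.007),
      r = c(1.00, 0.000, 0.010), r2 = c(0.45, 0.035, 0.012),
      t = c(-0.20, 0.23, 0.045)
    ),
    V = list( # wide ventricular complex, no P wave, inverted T
      r = c(1.20, 0.000, 0.024), s = c(-0.45, 0.055, 0.020),
      t = c(-0.35, 0.26, 0.055)
    ),
    P = list( # pacing spike then wide paced complex
      spike = c(0.50, -0.045, 0.0025), r = c(1.00, 0.000, 0.020),
      s = c(-0.30, 0.050, 0.016), t = c(-0.25, 0.24, 0.050)
    ),
    A = list( # atrial premature: normal-shaped, early P close to the QRS
      p = c(0.18, -0.12, 0.016), q = c(-0.10, -0.023, 0.006),
      r = c(0.95, 0.000, 0.009), s = c(-0.20, 0.025, 0.007),
      t = c(0.28, 0.21, 0.042)
    ),
    stop("no template for morphology ", morphology, call. = FALSE)
  )
}

# Longest template support on either side of the apex, in seconds.
template_halfspan_s <- 0.42

#' Generate a synthetic ECG with known R-peak ground truth
#'
#' @param spec A [synth_spec()].
#' @return A list with `record` (an [ecg_record()]) and `truth` (a
#'   [beat_annotations()] tibble whose positions are the exact R apex
#'   samples).
#' @examples
#' out <- generate_ecg(synth_spec(duration_s = 10, seed = 7))
#' nrow(out$truth)
#' @export
generate_ecg <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  fs <- spec$fs
  n <- as.integer(round(spec$duration_s * fs))
  rng <- local_rng(spec$seed)

  rr_nominal <- 60 / spec$heart_rate_bpm
  if (is.null(spec$rr_s)) {
    n_max <- ceiling(spec$duration_s / rr_nominal) + 2L
    jit <- rng$runif(n_max, -spec$rr_jitter_fraction, spec$rr_jitter_fraction)
    rr <- rr_nominal * (1 + jit)
  } else {
    rr <- spec$rr_s
  }
  if (any(rr <= 0.2)) {
    stop("RR intervals must exceed the 200 ms refractory period.", call. = FALSE)
  }
  if (any(rr < 2 * template_halfspan_s)) {
    stop("RR intervals shorter than the beat template support (",
      2 * template_halfspan_s, " s).",
      call. = FALSE
    )
  }
  apex_t <- cumsum(c(template_halfspan_s + 0.05, rr))
  apex_t <- apex_t[apex_t < spec$duration_s - template_halfspan_s]
  n_beats <- length(apex_t)
  if (n_beats == 0L) {
    stop("record too short to hold a single beat template.", call. = FALSE)
  }
  morph <- rep_len(spec$morphology, n_beats)
  apex_sample <- as.integer(round(apex_t * fs)) # 0-based
  apex_t <- apex_sample / fs # snap apexes onto the sample grid

  t <- (seq_len(n) - 1L) / fs
  x <- numeric(n)
  for (b in seq_len(n_beats)) {
    for (bump in beat_template(morph[[b]])) {
      ctr <- apex_t[[b]] + bump[[2L]]
      lo <- max(1L, floor((ctr - 5 * bump[[3L]]) * fs) + 1L)
      hi <- min(n, ceiling((ctr + 5 * bump[[3L]]) * fs) + 1L)
      idx <- lo:hi
      x[idx] <- x[idx] + bump[[1L]] * exp(-((t[idx] - ctr)^2) / (2 * bump[[3L]]^2))
    }
  }
  if (spec$baseline_amp_mv > 0) {
    x <- x + spec$baseline_amp_mv * sin(2 * pi * spec$baseline_freq_hz * t)
  }
  if (spec$noise_mv > 0) {
    x <- x + rng$rnorm(n, 0, spec$noise_mv)
  }
  symbol <- ifelse(morph == "P", "/", morph)
  list(
    record = ecg_record(x,
      fs = fs,
      record_id = sprintf("synth-%d", spec$seed)
    ),
    truth = beat_annotations(apex_sample, symbol)
  )
}

# Seed-scoped RNG: uses and restores the global .Random.seed so generators
# are reproducible without disturbing the caller's RNG state.
local_rng <- function(seed) {
  list(
    runif = function(n, min = 0, max = 1) {
      withr::with_seed(seed, stats::runif(n, min, max))
    },
    rnorm = function(n, mean = 0, sd = 1) {
      withr::with_seed(seed + 1L, stats::rnorm(n, mean, sd))
    }
  )
}

#' Generate band-limited muscle-artifact-like noise
#'
#' Zero-mean Gaussian noise band-passed to `[band_low_hz, band_high_hz]`
#' (default 20-120 Hz, overlapping QRS spectral content — the property
#' that makes muscular noise hard for QRS detectors) and normalized to
#' unit first-difference power so scaling factors act on a known baseline.
#'
#' @param fs Sampling frequency in Hz.
#' @param duration_s Duration in seconds.
#' @param band_low_hz,band_high_hz Pass band in Hz; `band_high_hz` is
#'   capped at `0.95 * fs / 2` and must stay below Nyquist.
#' @param seed Integer seed.
#' @return An [ecg_record()] with `record_id = "synthetic-ma"`.
#' @export
generate_muscle_noise <- function(fs = 360, duration_s = 30, band_low_hz = 20,
                                  band_high_hz = 120, seed = 1L) {
  stopifnot(fs > 0, duration_s > 0, band_low_hz > 0)
  band_high_hz <- min(band_high_hz, 0.95 * fs / 2)
  if (band_high_hz >= fs / 2) {
    stop("`band_high_hz` must lie below the Nyquist frequency.", call. = FALSE)
  }
  if (band_low_hz >= band_high_hz) {
    stop("`band_low_hz` must lie below `band_high_hz`.", call. = FALSE)
  }
  n <- as.integer(round(duration_s * fs))
  w <- withr::with_seed(as.integer(seed), stats::rnorm(n))
  bf <- signal::butter(4, c(band_low_hz, band_high_hz) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, w)
  x <- x - mean(x)
  x <- x / sqrt(difference_power(x))
  ecg_record(x, fs = fs, record_id = "synthetic-ma")
}
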