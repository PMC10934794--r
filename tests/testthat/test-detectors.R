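test_that("an all-zero signal produces no detections in any filter-based detector", {
  rec <- ecg_record(rep(0, 3600) + 0, fs = 360, record_id = "flat")
  rec$samples <- rep(0, 3600)
  expect_identical(nrow(detect_alg1(rec)), 0L)
  expect_identical(nrow(detect_alg2(rec)), 0L)
  expect_identical(nrow(detect_alg3(rec)), 0L) # constant: no level crossings
  expect_identical(nrow(detect_alg4(rec)), 0L)
})

test_that("every detector finds all pulses of a clean 60 bpm train near their apexes", {
  tr <- pulse_train(n_pulses = 10L, period_s = 1)
  tol <- c(`1` = 20L, `2` = 20L, `3` = 30L, `4` = 20L)
  for (alg in 1:4) {
    det <- detect_qrs(tr$record, alg)
    expect_identical(nrow(det), 10L)
    off <- det$sample - tr$truth_sample
    expect_true(all(abs(off) <= tol[[as.character(alg)]]),
      label = sprintf("algorithm %d offsets within %d samples", alg, tol[[as.character(alg)]])
    )
  }
})

test_that("two pulses 100 ms apart yield a single Algorithm 1 detection", {
  fs <- 360
  t <- (0:(3 * fs - 1)) / fs
  x <- exp(-((t - 1.0)^2) / (2 * 0.02^2)) + exp(-((t - 1.1)^2) / (2 * 0.02^2))
  rec <- ecg_record(x, fs = fs, record_id = "close-pair")
  det <- detect_alg1(rec)
  expect_identical(nrow(det), 1L)
})

test_that("Algorithm 2 detections are invariant under amplitude scaling", {
  tr <- pulse_train(n_pulses = 10L)
  det1 <- detect_alg2(tr$record)
  doubled <- tr$record
  doubled$samples <- 2 * doubled$samples
  det2 <- detect_alg2(doubled)
  expect_identical(det1$sample, det2$sample)
})

test_that("LC-ADC event stream follows the level-crossing and hysteresis rules", {
  p <- alg3_params(resolution_bits = 3L, k_l = 2L) # 7 levels
  # constant signal: no events
  const <- ecg_record(rep(1, 100) * 0 + 2, fs = 360)
  const$samples <- rep(2, 100)
  expect_identical(nrow(lc_adc_sample(const, p)), 0L)

  # monotone ramp: one event per level crossed, all ascending
  ramp <- ecg_record(seq(0, 1, length.out = 200), fs = 360)
  ev <- lc_adc_sample(ramp, p)
  expect_identical(nrow(ev), 6L) # starts on level 1, crosses levels 2..7
  expect_true(all(ev$direction == 1L))
  expect_identical(ev$level, 2:7)
  expect_true(all(ev$dv == "01"))

  # triangle: descending events only after k_l = 2 levels crossed downward
  tri <- ecg_record(c(seq(0, 1, length.out = 100), seq(1, 0, length.out = 100)[-1]),
    fs = 360
  )
  ev <- lc_adc_sample(tri, alg3_params(resolution_bits = 3L, k_l = 2L))
  first_down <- ev[ev$direction == 0L, ][1L, ]
  expect_identical(first_down$dv, "11") # reversal after a maximum
  expect_identical(first_down$level, 5L) # apex level 7 minus k_l = 2
  # the hand trace: ascending 2..7 then the first down event at level 5
  expect_identical(ev$level[1:7], c(2:7, 5L))
})

test_that("timer field wraps modulo 2^timer_bits", {
  fs <- 360
  # two slow ramps separated by a long plateau > 2048 samples
  x <- c(
    seq(0, 1, length.out = 50), rep(1, 2500),
    seq(1, 0, length.out = 50)
  )
  rec <- ecg_record(x, fs = fs)
  ev <- lc_adc_sample(rec, alg3_params(resolution_bits = 3L, k_l = 1L))
  gaps <- diff(ev$sample)
  expect_true(any(gaps > 2048L))
  expect_identical(ev$dt11[-1L], as.integer(gaps %% 2048L))
  expect_true(all(ev$dt11 >= 0L & ev$dt11 < 2048L))
})

test_that("Algorithm 3 detects tall narrow pulses and rejects unattainable spans", {
  tr <- pulse_train(n_pulses = 10L, width_s = 0.015)
  det <- detect_alg3(tr$record)
  expect_identical(nrow(det), 10L)
  expect_true(all(abs(det$sample - tr$truth_sample) <= 30L))

  # l_min above the whole level grid is unsatisfiable by construction
  none <- detect_alg3(tr$record, alg3_params(l_min = 300L))
  expect_identical(nrow(none), 0L)
})

test_that("Algorithm 4 respects the refractory period and an empty gap stays empty", {
  tr <- pulse_train(n_pulses = 10L)
  det <- detect_alg4(tr$record)
  expect_identical(nrow(det), 10L)
  expect_true(all(diff(det$sample) >= 72L)) # 200 ms at 360 Hz

  # remove one pulse: searchback must not invent a beat in a flat gap
  fs <- 360
  t <- (seq_len(11 * fs) - 1) / fs
  centers <- setdiff(1:10, 6L)
  x <- rowSums(vapply(
    centers,
    function(ctr) exp(-((t - ctr)^2) / (2 * 0.02^2)),
    numeric(length(t))
  ))
  rec <- ecg_record(x, fs = fs, record_id = "gap")
  det_gap <- detect_alg4(rec)
  expect_identical(nrow(det_gap), 9L)
  in_gap <- det_gap$sample > 5.3 * fs & det_gap$sample < 6.7 * fs
  expect_false(any(in_gap))
})

test_that("Algorithm 4 band-pass drives a DC input to zero", {
  rec <- ecg_record(rep(1, 2000), fs = 360)
  rec$samples <- rep(1, 2000)
  feat <- qrsbench:::alg4_feature(rec)
  expect_lt(max(abs(feat[500:1500])), 1e-12)
})

test_that("detectors are deterministic, sorted, refractory-gapped, and offset invariant", {
  out <- generate_ecg(synth_spec(
    duration_s = 20, seed = 31,
    morphology = c("N", "V", "N", "P", "L", "R", "A")
  ))
  rec <- out$record
  refr <- 72L
  for (alg in 1:4) {
    d1 <- detect_qrs(rec, alg)
    d2 <- detect_qrs(rec, alg)
    expect_identical(d1$sample, d2$sample)
    expect_true(all(diff(d1$sample) >= refr))
    expect_true(all(diff(d1$sample) > 0L))

    shifted <- rec
    shifted$samples <- rec$samples + 0.75
    d3 <- detect_qrs(shifted, alg)
    expect_identical(d1$sample, d3$sample)
  }
})

test_that("too-short records raise argument errors", {
  short <- ecg_record(sin(1:50 / 3), fs = 360)
  expect_error(detect_alg1(short), "at least")
  expect_error(detect_alg2(short), "at least")
  expect_error(detect_alg4(short), "at least")
})
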