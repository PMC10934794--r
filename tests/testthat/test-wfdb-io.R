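test_that("record write/read round trip preserves fs and samples to one ADC step", {
  dir <- withr::local_tempdir()
  x <- sin(2 * pi * 5 * (0:719) / 360) + 0.3 * cos(2 * pi * 1.1 * (0:719) / 360)
  rec <- ecg_record(x, fs = 360, record_id = "rt16", gain = 200)
  write_wfdb_record(rec, dir)
  back <- read_wfdb_record(file.path(dir, "rt16"))
  expect_identical(back$fs, 360)
  expect_identical(length(back$samples), length(x))
  expect_lte(max(abs(back$samples - x)), 1 / rec$gain)

  rec212 <- ecg_record(x, fs = 360, record_id = "rt212", gain = 200)
  write_wfdb_record(rec212, dir, format = "212")
  back212 <- read_wfdb_record(file.path(dir, "rt212"))
  expect_identical(length(back212$samples), length(x))
  expect_lte(max(abs(back212$samples - x)), 1 / rec212$gain)
})

test_that("a two-sample record survives the round trip exactly", {
  dir <- withr::local_tempdir()
  rec <- ecg_record(c(0.5, -0.25), fs = 100, record_id = "tiny", gain = 400)
  write_wfdb_record(rec, dir)
  back <- read_wfdb_record(file.path(dir, "tiny"))
  expect_identical(back$samples, c(0.5, -0.25))
  expect_identical(back$fs, 100)
})

test_that("degenerate headers and arguments are rejected", {
  dir <- withr::local_tempdir()
  writeLines("empty 0 360 100", file.path(dir, "empty.hea"))
  expect_error(read_wfdb_record(file.path(dir, "empty")), "no signals")
  expect_error(read_wfdb_record(file.path(dir, "absent")), "not found")
  expect_error(ecg_record(1:10, fs = 0), "fs")
  x <- sin(1:720 / 10)
  rec <- ecg_record(x, fs = 360, record_id = "chan", gain = 100)
  write_wfdb_record(rec, dir)
  expect_error(read_wfdb_record(file.path(dir, "chan"), channel = 1), "out of range")
})

test_that("length mismatch between header and signal file is detected", {
  dir <- withr::local_tempdir()
  rec <- ecg_record(sin(1:360 / 5), fs = 360, record_id = "mis", gain = 100)
  write_wfdb_record(rec, dir)
  hea <- readLines(file.path(dir, "mis.hea"))
  hea[1] <- "mis 1 360 500"
  writeLines(hea, file.path(dir, "mis.hea"))
  expect_error(read_wfdb_record(file.path(dir, "mis")), "declares")
})

test_that("annotation write/read round trips through the MIT binary format", {
  dir <- withr::local_tempdir()
  # gap > 1023 samples exercises the SKIP pseudo-annotation encoding
  ann <- beat_annotations(
    c(10L, 400L, 2000L, 2200L, 100000L),
    c("N", "/", "V", "A", "L")
  )
  path <- file.path(dir, "rt.atr")
  write_wfdb_annotations(ann, path)
  back <- read_wfdb_annotations(path)
  expect_identical(back$sample, ann$sample)
  expect_identical(back$symbol, ann$symbol)
  expect_identical(as.character(back$morphology), c("N", "P", "V", "A", "L"))
})

test_that("non-beat annotations are discarded by the reader", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "nonbeat.atr")
  # rhythm change (code 28) at t=10, note (code 22) at t=50, then EOF
  words <- c(bitwOr(bitwShiftL(28L, 10L), 10L), bitwOr(bitwShiftL(22L, 10L), 40L), 0L)
  con <- file(path, "wb")
  for (w in words) writeBin(as.raw(c(w %% 256L, w %/% 256L)), con)
  close(con)
  out <- read_wfdb_annotations(path)
  expect_identical(nrow(out), 0L)

  # mixed file: beat annotations survive, the rhythm marker does not
  mixed <- file.path(dir, "mixed.atr")
  words <- c(
    bitwOr(bitwShiftL(1L, 10L), 10L), # N at 10
    bitwOr(bitwShiftL(28L, 10L), 5L), # rhythm marker (advances time)
    bitwOr(bitwShiftL(12L, 10L), 385L), # "/" at 400
    0L
  )
  con <- file(mixed, "wb")
  for (w in words) writeBin(as.raw(c(w %% 256L, w %/% 256L)), con)
  close(con)
  out <- read_wfdb_annotations(mixed)
  expect_identical(out$sample, c(10L, 400L))
  expect_identical(as.character(out$morphology), c("N", "P"))
})

test_that("annotation positions come back strictly sorted from shuffled CSV input", {
  dir <- withr::local_tempdir()
  withr::with_seed(99, {
    for (rep in 1:20) {
      pos <- sort(sample.int(50000L, 40L))
      sym <- sample(c("N", "L", "R", "V", "/", "A", "f"), 40L, replace = TRUE)
      shuf <- sample.int(40L)
      path <- file.path(dir, "shuffled.csv")
      utils::write.csv(
        data.frame(sample = pos[shuf], symbol = sym[shuf]),
        path,
        row.names = FALSE, quote = FALSE
      )
      out <- read_wfdb_annotations(path)
      expect_true(all(diff(out$sample) > 0L))
      expect_identical(out$sample, pos)
      expect_identical(out$symbol, sym)
    }
  })
})

test_that("morphology mapping is total over beat symbols and targets the six classes", {
  morph <- map_morphology(qrsbench:::wfdb_beat_symbols)
  expect_false(anyNA(morph))
  expect_identical(as.character(map_morphology("/")), "P")
  expect_identical(
    as.character(map_morphology(c("N", "L", "R", "V", "A"))),
    c("N", "L", "R", "V", "A")
  )
  # everything else collapses to OTHER; non-beat symbols are NA
  expect_identical(as.character(map_morphology(c("f", "F", "j", "Q"))), rep("OTHER", 4))
  expect_true(is.na(map_morphology("+")))
})

test_that("detections CSV round trips", {
  dir <- withr::local_tempdir()
  tr <- pulse_train(n_pulses = 5L)
  det <- detect_alg1(tr$record)
  path <- file.path(dir, "det.csv")
  write_detections_csv(det, path)
  back <- read_detections_csv(path)
  expect_identical(back$sample, det$sample)
  expect_identical(unique(back$record_id), "pulse-train")
})

test_that("noise-mixed record round trip preserves the achieved SNR within 0.1 dB", {
  dir <- withr::local_tempdir()
  ecg <- generate_ecg(synth_spec(duration_s = 10, seed = 5))$record
  noise <- generate_muscle_noise(duration_s = 10, seed = 6)
  esnr <- relative_snr(difference_power(ecg), difference_power(noise))
  k <- scaling_factor(esnr, 7, mode = "power-consistent")
  mixed <- mix_noise(ecg, noise, k)
  pre <- relative_snr(
    difference_power(ecg$samples),
    difference_power(k * noise$samples)
  )
  mixed$record_id <- "mix10"
  mixed$gain <- 1000
  write_wfdb_record(mixed, dir)
  reread <- read_wfdb_record(file.path(dir, "mix10"))
  scaled_noise <- reread$samples - ecg$samples
  post <- relative_snr(
    difference_power(ecg$samples),
    difference_power(scaled_noise)
  )
  expect_lt(abs(post - pre), 0.1)
})
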