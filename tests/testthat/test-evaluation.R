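test_that("matching handles the exact and hopeless extremes", {
  ann <- c(100L, 500L, 900L)
  m <- match_detections(ann, ann, 3L)
  expect_identical(c(m$tp, m$fn, m$fp), c(3L, 0L, 0L))
  expect_identical(m$pairs$offset, c(0L, 0L, 0L))

  m2 <- match_detections(ann + 4L, ann, 3L)
  expect_identical(c(m2$tp, m2$fn, m2$fp), c(0L, 3L, 3L))

  expect_error(match_detections(c(5L, 1L), ann, 3L), "sorted")
  expect_error(match_detections(ann, ann, 0L), "positive")
})

test_that("two-pointer matching equals exhaustive maximum bipartite matching", {
  withr::with_seed(42, {
    for (rep in 1:200) {
      inst <- random_match_instance(max_points = 12L)
      tol <- sample(c(1L, 3L, 7L, 17L, 40L), 1L)
      m <- match_detections(inst$det, inst$ann, tol)
      expect_identical(
        m$tp,
        oracle_max_matching(inst$ann, inst$det, tol)
      )
      # pairing is one-to-one and within tolerance
      expect_identical(anyDuplicated(m$pairs$annotation_index), 0L)
      expect_identical(anyDuplicated(m$pairs$detection_index), 0L)
      expect_true(all(abs(m$pairs$offset) <= tol))
      # conservation
      expect_identical(m$tp + m$fn, length(inst$ann))
      expect_identical(m$tp + m$fp, length(inst$det))
    }
  })
})

test_that("TP is nondecreasing across the DTT grid", {
  grid <- c(3L, 17L, 31L, 45L, 59L)
  withr::with_seed(43, {
    for (rep in 1:50) {
      inst <- random_match_instance(max_points = 12L, span = 1000L)
      tps <- vapply(
        grid,
        function(tol) match_detections(inst$det, inst$ann, tol)$tp,
        integer(1)
      )
      expect_true(all(diff(tps) >= 0L))
    }
  })
})

test_that("raising the tolerance converts an FN/FP pair into one TP", {
  ann <- c(100L, 500L)
  det <- c(100L, 504L)
  m3 <- match_detections(det, ann, 3L)
  m4 <- match_detections(det, ann, 4L)
  expect_identical(m4$tp - m3$tp, 1L)
  expect_identical(m3$fn - m4$fn, 1L)
  expect_identical(m3$fp - m4$fp, 1L)
})

test_that("metric formulas and the F1 harmonic identity hold", {
  m <- qrs_metrics(9, 1, 1, 10)
  expect_equal(m$se, 90)
  expect_equal(m$ppv, 90)
  expect_equal(m$f1, 90)
  expect_equal(m$der, 0.2)
  expect_equal(m$tp_tb, 90)

  perfect <- qrs_metrics(10, 0, 0, 10)
  expect_equal(unlist(perfect[c("se", "ppv", "f1")]), c(se = 100, ppv = 100, f1 = 100))
  expect_equal(perfect$der, 0)

  zero <- qrs_metrics(0, 0, 0, 0)
  expect_true(all(is.na(unlist(zero))))

  withr::with_seed(44, {
    for (rep in 1:30) {
      tp <- sample.int(50, 1)
      fn <- sample.int(50, 1)
      fp <- sample.int(50, 1)
      got <- qrs_metrics(tp, fn, fp, tp + fn)
      se <- tp / (tp + fn)
      ppv <- tp / (tp + fp)
      expect_equal(got$f1, 100 * 2 / (1 / se + 1 / ppv), tolerance = 1e-12)
    }
  })
})

test_that("sample counts convert to the printed millisecond values", {
  expect_equal(round(samples_to_ms(3, 360), 2), 8.33)
  expect_equal(round(samples_to_ms(59, 360), 2), 163.89)
  expect_equal(
    round(samples_to_ms(c(3, 17, 31, 45, 59), 360), 2),
    c(8.33, 47.22, 86.11, 125.00, 163.89)
  )
  expect_identical(samples_to_ms(0, 360), 0)
  expect_error(samples_to_ms(3, 0), "positive")
})

test_that("stratification filters the tally but not the matching", {
  ann <- beat_annotations(
    c(100L, 400L, 700L, 1000L, 1300L),
    c("N", "V", "N", "/", "N")
  )
  det <- c(101L, 399L, 1002L) # hits beats 1, 2, 4
  m <- match_detections(det, ann, 3L)
  s <- stratify_matches(m, ann)
  expect_identical(s$tb[s$morphology == "N"], 3L)
  expect_identical(s$tp[s$morphology == "N"], 1L)
  expect_identical(s$tp[s$morphology == "V"], 1L)
  expect_identical(s$tp[s$morphology == "P"], 1L)
  expect_identical(s$tb[s$morphology == "L"], 0L)
  expect_true(is.na(s$tp_tb[s$morphology == "L"]))
  expect_equal(s$tp_tb[s$morphology == "N"], 100 / 3)

  perfect <- match_detections(ann$sample, ann, 3L)
  sp <- stratify_matches(perfect, ann)
  expect_true(all(sp$tp_tb[sp$tb > 0] == 100))
})

test_that("a detection near an excluded-morphology beat is not recounted elsewhere", {
  ann <- beat_annotations(c(100L, 110L), c("f", "N")) # f pools into OTHER
  det <- c(101L)
  m <- match_detections(det, ann, 3L)
  s <- stratify_matches(m, ann, morphology = c("N", "OTHER"))
  expect_identical(s$tp[s$morphology == "OTHER"], 1L)
  expect_identical(s$tp[s$morphology == "N"], 0L)
})

test_that("aggregation pools records first, then averages strata", {
  base <- tidyr::expand_grid(
    algorithm = 1:2, dtt_samples = c(3L, 17L),
    noise_level = c("none", "3dB"), morphology = c("N", "V"),
    record_id = c("a", "b")
  )
  all100 <- dplyr::mutate(base, tb = 10L, tp = 10L)
  agg <- aggregate_tp_tb(all100, c("algorithm", "dtt_samples"))
  expect_true(all(agg$mean == 100))
  expect_true(all(agg$std == 0))
  expect_true(all(agg$n_values == 4L))

  # {0, 100} across two pooled strata: mean 50, population std 50
  two <- dplyr::mutate(
    dplyr::filter(base, algorithm == 1L, dtt_samples == 3L, morphology == "N"),
    tb = 10L, tp = dplyr::if_else(noise_level == "none", 10L, 0L)
  )
  agg2 <- aggregate_tp_tb(two,
    fixed_axes = "algorithm",
    summarized_axes = "noise_level"
  )
  expect_equal(agg2$mean, 50)
  expect_equal(agg2$std, 50)

  # random grid against a flat independent recomputation
  withr::with_seed(45, {
    rnd <- dplyr::mutate(base,
      tb = sample(5:20, dplyr::n(), replace = TRUE),
      tp = vapply(tb, function(t) sample.int(t + 1L, 1L) - 1L, integer(1))
    )
    agg3 <- aggregate_tp_tb(rnd, c("algorithm", "dtt_samples"))
    for (r in seq_len(nrow(agg3))) {
      sub <- rnd[rnd$algorithm == agg3$algorithm[r] &
        rnd$dtt_samples == agg3$dtt_samples[r], ]
      vals <- vapply(
        split(sub, paste(sub$noise_level, sub$morphology)),
        function(g) 100 * sum(g$tp) / sum(g$tb),
        numeric(1)
      )
      expect_equal(agg3$mean[r], mean(vals), tolerance = 1e-12)
      expect_equal(agg3$std[r], sqrt(mean((vals - mean(vals))^2)), tolerance = 1e-12)
    }
  })

  # missing cells are reported
  holed <- dplyr::filter(all100, !(algorithm == 2L & noise_level == "3dB"))
  expect_error(
    aggregate_tp_tb(holed, c("algorithm", "noise_level")),
    "missing cells"
  )
})

test_that("per-record reports total correctly and flag improvements", {
  grid <- tidyr::expand_grid(
    algorithm = 1L, dtt_samples = 3L,
    noise_level = c("none", "15dB", "7dB"), morphology = "N",
    record_id = c("a", "b")
  )
  grid$tb <- 100L
  # record a: 90/80/70 across none/15/7 dB; record b: 50/60/55 (improves at 15 dB)
  grid$tp <- c(90L, 50L, 80L, 60L, 70L, 55L)
  rep_tbl <- per_record_report(grid, 1L, "N", 3L)
  tot <- rep_tbl[rep_tbl$record_id == "TOTAL", ]
  expect_identical(tot$tb, 200L)
  expect_identical(tot$tp_none, 140L)
  expect_identical(tot$`tp_15dB`, 140L)
  expect_identical(rep_tbl$`delta_15dB`, c(-10L, 10L, 0L))
  expect_identical(rep_tbl$improved, c(FALSE, TRUE, FALSE))

  flat <- dplyr::mutate(grid[grid$record_id == "a", ], tp = 75L)
  rep_flat <- per_record_report(flat, 1L, "N", 3L)
  expect_true(all(rep_flat$`delta_15dB` == 0L))
  expect_true(all(rep_flat$`delta_7dB` == 0L))
})

test_that("tidy and glance expose the pairing and the metric summary", {
  ann <- beat_annotations(c(100L, 500L), c("N", "N"))
  m <- match_detections(c(101L, 600L), ann, 5L)
  expect_identical(nrow(tidy(m)), 1L)
  g <- glance(m)
  expect_identical(g$tp, 1L)
  expect_equal(g$se, 50)
  expect_equal(g$ppv, 50)
})
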