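#' Convert sample counts to milliseconds
#'
#' @param n Number of samples (vectorized).
#' @param fs Sampling frequency in Hz (positive).
#' @return `n * 1000 / fs`, in ms. At 360 Hz, 3 samples are 8.33 ms and 59
#'   samples are 163.89 ms (2 dp).
#' @export
samples_to_ms <- function(n, fs) {
  if (!is.numeric(fs) || any(fs <= 0)) stop("`fs` must be positive.", call. = FALSE)
  n * 1000 / fs
}

#' Match detections against reference annotations at a temporal tolerance
#'
#' Computes a maximum-cardinality one-to-one pairing between annotated and
#' detected R-peaks subject to `|detection - annotation| <=
#' tolerance_samples` (two-sided, inclusive), using the sorted two-pointer
#' matcher (optimal for interval constraints on a line; ties break toward
#' the earlier detection). Unmatched annotations are false negatives,
#' unmatched detections false positives.
#'
#' @param detections Integer vector of detected sample indices (sorted) or
#'   a [qrs_detections()] tibble.
#' @param annotations Integer vector of annotated sample indices (sorted)
#'   or a [beat_annotations()] tibble.
#' @param tolerance_samples Detection temporal tolerance (DTT) in samples,
#'   a positive integer. The benchmark grid is `c(3, 17, 31, 45, 59)`.
#' @return An object of class `qrs_match`: a list with `tp`, `fn`, `fp`,
#'   `tolerance_samples`, and `pairs`, a tibble with columns
#'   `annotation_index`, `detection_index` (1-based row indices into the
#'   inputs) and `offset` (detection minus annotation, in samples).
#' @examples
#' m <- match_detections(c(10L, 52L, 99L), c(10L, 50L, 90L), 3L)
#' glance(m)
#' @export
match_detections <- function(detections, annotations, tolerance_samples) {
  det <- if (inherits(detections, "qrs_detections")) detections$sample else as.integer(detections)
  ann <- if (inherits(annotations, "beat_annotations")) annotations$sample else as.integer(annotations)
  tol <- as.integer(tolerance_samples)
  if (length(tol) != 1L || is.na(tol) || tol < 1L) {
    stop("`tolerance_samples` must be a positive integer.", call. = FALSE)
  }
  if (is.unsorted(det, strictly = FALSE) || is.unsorted(ann, strictly = FALSE)) {
    stop("detections and annotations must be sorted.", call. = FALSE)
  }
  na <- length(ann)
  nd <- length(det)
  ai <- integer(0)
  di <- integer(0)
  i <- 1L
  j <- 1L
  while (i <= na && j <= nd) {
    d <- det[j] - ann[i]
    if (abs(d) <= tol) {
      ai <- c(ai, i)
      di <- c(di, j)
      i <- i + 1L
      j <- j + 1L
    } else if (d > tol) {
      i <- i + 1L # annotation too far behind: FN
    } else {
      j <- j + 1L # detection too far behind: FP
    }
  }
  pairs <- tibble::tibble(
    annotation_index = ai,
    detection_index = di,
    offset = det[di] - ann[ai]
  )
  structure(
    list(
      tp = nrow(pairs), fn = na - nrow(pairs), fp = nd - nrow(pairs),
      n_annotations = na, n_detections = nd,
      tolerance_samples = tol, pairs = pairs
    ),
    class = "qrs_match"
  )
}

#' @export
print.qrs_match <- function(x, ...) {
  cat(sprintf(
    "<qrs_match>  DTT = %d samples: TP %d, FN %d, FP %d (of %d annotations, %d detections)\n",
    x$tolerance_samples, x$tp, x$fn, x$fp, x$n_annotations, x$n_detections
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a match result into its pairing table
#'
#' @param x A `qrs_match` object.
#' @param ... Unused.
#' @return The pairs tibble (`annotation_index`, `detection_index`,
#'   `offset`).
#' @method tidy qrs_match
#' @export
tidy.qrs_match <- function(x, ...) x$pairs

#' One-row summary of a match result
#'
#' @param x A `qrs_match` object.
#' @param ... Unused.
#' @return A one-row tibble with counts and the derived metrics of
#'   [qrs_metrics()].
#' @method glance qrs_match
#' @export
glance.qrs_match <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      tolerance_samples = x$tolerance_samples,
      tp = x$tp, fn = x$fn, fp = x$fp
    ),
    qrs_metrics(x$tp, x$fn, x$fp, x$n_annotations)
  )
}

#' Detection performance metrics
#'
#' Sensitivity `Se = TP/(TP+FN)`, positive predictivity
#' `PPV = TP/(TP+FP)`, `F1 = 2 PPV Se / (Se + PPV)`,
#' detection error rate `DER = (FN+FP)/TB`, and the benchmark's headline
#' accuracy `TP/TB`. Percentages are reported on the 0-100 scale; DER is a
#' plain ratio. A zero denominator yields `NA` rather than an error.
#'
#' @param tp,fn,fp,tb Non-negative integer counts (vectorized).
#' @return A tibble with columns `se`, `ppv`, `f1`, `der`, `tp_tb`.
#' @examples
#' qrs_metrics(9, 1, 1, 10)
#' @export
qrs_metrics <- function(tp, fn, fp, tb) {
  if (any(c(tp, fn, fp, tb) < 0)) {
    stop("counts must be non-negative.", call. = FALSE)
  }
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  se <- 100 * safe_div(tp, tp + fn)
  ppv <- 100 * safe_div(tp, tp + fp)
  f1 <- ifelse(!is.na(se) & !is.na(ppv) & (se + ppv) > 0,
    2 * ppv * se / (se + ppv), NA_real_
  )
  tibble::tibble(
    se = se, ppv = ppv, f1 = f1,
    der = safe_div(fn + fp, tb),
    tp_tb = 100 * safe_div(tp, tb)
  )
}

#' Morphology-stratified TP/TB tally
#'
#' Matching is always performed against the *full* annotation set (so a
#' detection near a beat of another class cannot be re-counted elsewhere);
#' stratification only filters the tally: `tb` counts the annotations
#' carrying each morphology label and `tp` the matched pairs whose
#' annotation carries it. Strata with `tb = 0` carry `tp_tb = NA` and are
#' excluded from aggregation.
#'
#' @param match A `qrs_match` from [match_detections()].
#' @param annotations The [beat_annotations()] the match was computed
#'   against.
#' @param morphology Character vector of classes to tally (default the six
#'   tracked classes).
#' @return A tibble with columns `morphology`, `tb`, `tp`, `tp_tb`.
#' @export
stratify_matches <- function(match, annotations,
                             morphology = setdiff(morphology_levels, "OTHER")) {
  stopifnot(inherits(match, "qrs_match"), inherits(annotations, "beat_annotations"))
  if (match$n_annotations != nrow(annotations)) {
    stop("`annotations` is not the set the match was computed against.",
      call. = FALSE
    )
  }
  matched_label <- as.character(annotations$morphology[match$pairs$annotation_index])
  all_label <- as.character(annotations$morphology)
  purrr::map_dfr(morphology, function(m) {
    tb <- sum(all_label == m)
    tp <- sum(matched_label == m)
    tibble::tibble(
      morphology = m, tb = tb, tp = tp,
      tp_tb = if (tb > 0) 100 * tp / tb else NA_real_
    )
  })
}

#' Aggregate a TP/TB evaluation grid into mean/std summary cells
#'
#' Reproduces the benchmark's summary-table scheme: per cell of
#' `fixed_axes`, the per-record counts are pooled (summed over records)
#' within each combination of `summarized_axes`, pooled `tp_tb` values are
#' formed, and their mean and population standard deviation reported.
#' The three canonical layouts fix (algorithm, DTT) and summarize
#' morphology x noise (24 values per cell), fix (algorithm, morphology)
#' over DTT x noise (20 values), and fix (algorithm, noise) over
#' morphology x DTT (30 values).
#'
#' @param grid An evaluation grid tibble with columns `algorithm`,
#'   `dtt_samples`, `noise_level`, `morphology`, `record_id`, `tb`, `tp`
#'   (one row per stratum per record), as produced by [run_sweep()].
#' @param fixed_axes Character vector of grid axes to keep as cell
#'   identifiers.
#' @param summarized_axes Axes whose pooled values are averaged; defaults
#'   to the remaining non-record axes.
#' @return A tibble with the fixed axes plus `mean`, `std` (population) and
#'   `n_values`.
#' @export
aggregate_tp_tb <- function(grid, fixed_axes,
                            summarized_axes = setdiff(
                              c("algorithm", "dtt_samples", "noise_level", "morphology"),
                              fixed_axes
                            )) {
  axes <- c("algorithm", "dtt_samples", "noise_level", "morphology")
  if (!all(fixed_axes %in% axes) || !all(summarized_axes %in% axes)) {
    stop("axes must be drawn from: ", paste(axes, collapse = ", "), call. = FALSE)
  }
  need <- union(fixed_axes, summarized_axes)
  missing_cells <- grid |>
    dplyr::distinct(dplyr::across(dplyr::all_of(need)))
  full <- do.call(
    tidyr::expand_grid,
    lapply(stats::setNames(need, need), function(a) unique(grid[[a]]))
  )
  absent <- dplyr::anti_join(full, missing_cells, by = need)
  if (nrow(absent) > 0L) {
    stop(
      "grid does not cover the requested axes; missing cells:\n",
      paste(utils::capture.output(print(as.data.frame(absent))), collapse = "\n"),
      call. = FALSE
    )
  }
  pooled <- grid |>
    dplyr::group_by(dplyr::across(dplyr::all_of(need))) |>
    dplyr::summarise(tb = sum(.data$tb), tp = sum(.data$tp), .groups = "drop") |>
    dplyr::filter(.data$tb > 0L) |>
    dplyr::mutate(tp_tb = 100 * .data$tp / .data$tb)
  pooled |>
    dplyr::group_by(dplyr::across(dplyr::all_of(fixed_axes))) |>
    dplyr::summarise(
      mean = mean(.data$tp_tb),
      std = stats::sd(.data$tp_tb) * sqrt((dplyr::n() - 1) / dplyr::n()),
      n_values = dplyr::n(),
      .groups = "drop"
    )
}

#' Per-record TP report across noise levels
#'
#' One row per record for a fixed (algorithm, morphology, DTT): TB, TP at
#' each noise level, TP deltas versus the no-added-noise column, an
#' `improved` flag for any positive delta, and a TOTAL row summing the
#' columns. Records without beats of the morphology are omitted.
#'
#' @param grid Evaluation grid as in [aggregate_tp_tb()].
#' @param algorithm,morphology,dtt_samples Cell selector.
#' @param baseline Noise level treated as the reference column (default
#'   `"none"`).
#' @return A tibble with columns `record_id`, `tb`, one `tp_<level>` per
#'   noise level, one `delta_<level>` per non-baseline level, `improved`.
#' @export
per_record_report <- function(grid, algorithm, morphology, dtt_samples,
                              baseline = "none") {
  cell <- grid |>
    dplyr::filter(
      .data$algorithm == !!algorithm,
      .data$morphology == !!morphology,
      .data$dtt_samples == !!dtt_samples,
      .data$tb > 0L
    )
  levels_present <- unique(cell$noise_level)
  if (!(baseline %in% levels_present)) {
    stop("baseline noise level '", baseline, "' not present in the grid.",
      call. = FALSE
    )
  }
  wide <- cell |>
    dplyr::select("record_id", "noise_level", "tb", "tp") |>
    tidyr::pivot_wider(
      names_from = "noise_level", values_from = "tp", names_prefix = "tp_"
    )
  total <- wide |>
    dplyr::summarise(
      record_id = "TOTAL",
      dplyr::across(dplyr::where(is.numeric), sum)
    )
  out <- dplyr::bind_rows(wide, total)
  base_col <- paste0("tp_", baseline)
  for (lev in setdiff(levels_present, baseline)) {
    out[[paste0("delta_", lev)]] <- out[[paste0("tp_", lev)]] - out[[base_col]]
  }
  delta_cols <- grep("^delta_", names(out), value = TRUE)
  out$improved <- if (length(delta_cols)) {
    apply(out[delta_cols] > 0, 1L, any)
  } else {
    FALSE
  }
  out
}
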