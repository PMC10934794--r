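#' Plot an evaluation grid as a DTT sweep
#'
#' Pooled (summed over records) TP/TB against DTT, faceted by morphology,
#' one line/colour per noise level, one panel row per algorithm — the
#' at-a-glance view of how quickly each detector's accuracy degrades as
#' the temporal tolerance shrinks.
#'
#' @param object A `qrs_eval_grid` tibble (the `grid` element of a
#'   [run_sweep()] result).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qrs_eval_grid
#' @export
autoplot.qrs_eval_grid <- function(object, ...) {
  pooled <- object |>
    dplyr::group_by(
      .data$algorithm, .data$dtt_samples, .data$noise_level, .data$morphology
    ) |>
    dplyr::summarise(tb = sum(.data$tb), tp = sum(.data$tp), .groups = "drop") |>
    dplyr::filter(.data$tb > 0L) |>
    dplyr::mutate(tp_tb = 100 * .data$tp / .data$tb)
  ggplot2::ggplot(
    pooled,
    ggplot2::aes(
      x = .data$dtt_samples, y = .data$tp_tb,
      colour = .data$noise_level, group = .data$noise_level
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$algorithm),
      cols = ggplot2::vars(.data$morphology),
      labeller = ggplot2::labeller(
        .rows = function(a) paste("Algorithm", a)
      )
    ) +
    ggplot2::labs(
      x = "detection temporal tolerance (samples)",
      y = "TP/TB (%)", colour = "added noise"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a segment of an ECG record with optional marks
#'
#' @param object An [ecg_record()].
#' @param annotations Optional [beat_annotations()] to mark as vertical
#'   lines.
#' @param detections Optional [qrs_detections()] to mark as points.
#' @param from_s,to_s Time window in seconds (defaults to the first 10 s).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ecg_record
#' @export
autoplot.ecg_record <- function(object, annotations = NULL, detections = NULL,
                                from_s = 0, to_s = min(10, record_duration(object)),
                                ...) {
  t <- (seq_along(object$samples) - 1L) / object$fs
  keep <- t >= from_s & t <= to_s
  df <- tibble::tibble(t = t[keep], mv = object$samples[keep])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (s)", y = sprintf("amplitude (%s)", object$units),
      title = sprintf("record %s", object$record_id)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(annotations)) {
    at <- annotations$sample / object$fs
    p <- p + ggplot2::geom_vline(
      xintercept = at[at >= from_s & at <= to_s],
      colour = "grey60", linetype = "dashed", linewidth = 0.3
    )
  }
  if (!is.null(detections)) {
    dt <- detections$sample / object$fs
    dt <- dt[dt >= from_s & dt <= to_s]
    idx <- as.integer(round(dt * object$fs)) + 1L
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(t = dt, mv = object$samples[idx]),
      colour = "red", size = 1.5
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
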