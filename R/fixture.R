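#' Write a miniature benchmark database to disk
#'
#' Generates a handful of synthetic records with ground-truth annotations,
#' a synthetic muscle-noise record, and one noise-mixed variant of every
#' record per target SNR — a self-contained miniature of a noise-stress
#' test dataset, in WFDB format plus a CSV manifest. Useful for end-to-end
#' harness tests and as the input layout expected by [run_sweep()].
#'
#' @param dir Output directory (created).
#' @param n_records Number of records (default 3).
#' @param duration_s Duration per record (default 30 s).
#' @param heart_rate_bpm Heart rate (default 60).
#' @param morphology Morphology sequences; either a single character
#'   vector recycled over beats for every record, or a list with one
#'   vector per record. Default gives each record a mix of the six
#'   classes.
#' @param targets Target SNRs in dB (default `c(15, 7, 3)`).
#' @param mode,snr_convention Mixing conventions, see [scaling_factor()].
#' @param seed Integer seed.
#' @return Invisibly, a list with `records`, `truths`, `noise`, `mixed`
#'   (the [build_noise_dataset()] result) and `manifest` (tibble).
#' @export
make_benchmark_fixture <- function(dir, n_records = 3L, duration_s = 30,
                                   heart_rate_bpm = 60,
                                   morphology = list(
                                     c("N", "N", "N", "V", "N", "A"),
                                     c("L", "L", "R", "R", "N", "N"),
                                     c("P", "P", "P", "N", "V", "N")
                                   ),
                                   targets = c(15, 7, 3),
                                   mode = "power-consistent",
                                   snr_convention = "printed",
                                   seed = 20L) {
  if (length(targets) == 0L) stop("`targets` must be non-empty.", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.list(morphology)) morphology <- list(morphology)
  gen <- purrr::map(seq_len(n_records), function(i) {
    sp <- synth_spec(
      duration_s = duration_s, heart_rate_bpm = heart_rate_bpm,
      morphology = morphology[[(i - 1L) %% length(morphology) + 1L]],
      seed = seed + 10L * i
    )
    out <- generate_ecg(sp)
    out$record$record_id <- sprintf("s%02d", i)
    out
  })
  records <- purrr::map(gen, "record")
  truths <- purrr::map(gen, "truth")
  names(truths) <- purrr::map_chr(records, "record_id")

  noise <- generate_muscle_noise(
    fs = records[[1L]]$fs, duration_s = duration_s, seed = seed + 1L
  )
  mixed <- build_noise_dataset(records, noise, targets,
    mode = mode, snr_convention = snr_convention
  )

  for (i in seq_along(records)) {
    rec <- records[[i]]
    write_wfdb_record(rec, dir)
    write_wfdb_annotations(truths[[rec$record_id]],
      file.path(dir, paste0(rec$record_id, ".atr"))
    )
    utils::write.csv(
      data.frame(
        sample = truths[[rec$record_id]]$sample,
        symbol = truths[[rec$record_id]]$symbol
      ),
      file.path(dir, paste0(rec$record_id, "_annotations.csv")),
      row.names = FALSE, quote = FALSE
    )
    for (tag in names(mixed[[rec$record_id]]$mixed)) {
      mrec <- mixed[[rec$record_id]]$mixed[[tag]]
      mrec$record_id <- paste0(rec$record_id, "_", tag)
      write_wfdb_record(mrec, dir)
    }
  }
  write_wfdb_record(noise, dir)
  manifest <- attr(mixed, "manifest")
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
    row.names = FALSE, quote = FALSE
  )
  invisible(list(
    records = records, truths = truths, noise = noise,
    mixed = mixed, manifest = manifest
  ))
}
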