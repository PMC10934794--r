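#' Published beat-morphology counts for the MIT-BIH Arrhythmia Database
#'
#' The per-class beat counts of the six most frequent QRS morphologies in
#' the MIT-BIH Arrhythmia Database (N, L, R, V, P, A) together with the
#' database-wide beat total, as published for the standard annotation
#' files. The `ALL` row counts every beat annotation in the database, not
#' only the six tracked classes; the six classes cover about 97.8% of it.
#'
#' @return A tibble with columns `morphology` and `count`; the `ALL` row
#'   is the total beat count.
#' @examples
#' counts <- mitdb_morphology_counts()
#' six <- counts[counts$morphology != "ALL", ]
#' 100 * sum(six$count) / counts$count[counts$morphology == "ALL"]
#' @export
mitdb_morphology_counts <- function() {
  path <- system.file("extdata", "mitdb_morphology_counts.csv",
    package = "qrsbench", mustWork = TRUE
  )
  df <- utils::read.csv(path, colClasses = c("character", "integer"))
  tibble::as_tibble(df)
}

#' Tally beat morphologies over a WFDB annotation directory
#'
#' Reads every annotation file matching `pattern` in `dir` through
#' [read_wfdb_annotations()] and tallies beats per morphology class and
#' per record. Pointing this at a local copy of the MIT-BIH Arrhythmia
#' Database reproduces the published class counts; the totals count every
#' beat annotation (all WFDB beat symbols), with symbols outside the six
#' tracked classes pooled into `OTHER`.
#'
#' @param dir Directory holding annotation files.
#' @param pattern Filename regular expression (default `"\\.atr$"`).
#' @return A tibble with columns `record_id`, `morphology`, `count`.
#' @export
tally_database_morphology <- function(dir, pattern = "\\.atr$") {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (length(files) == 0L) {
    stop("no annotation files matching '", pattern, "' under ", dir,
      call. = FALSE
    )
  }
  purrr::map_dfr(files, function(f) {
    ann <- read_wfdb_annotations(f)
    counts <- table(ann$morphology)
    tibble::tibble(
      record_id = sub("\\.[^.]*$", "", basename(f)),
      morphology = names(counts),
      count = as.integer(counts)
    )
  })
}
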