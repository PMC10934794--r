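#' Read WFDB beat annotations (MIT `.atr` format)
#'
#' Decodes the MIT annotation format: a stream of 16-bit little-endian
#' words whose upper 6 bits carry the annotation type code and lower 10
#' bits the time increment, with the standard pseudo-annotations (SKIP for
#' long intervals, NUM/SUB/CHN/AUX) handled and discarded. Only beat
#' annotations are returned; rhythm and signal-quality annotations are
#' dropped, because only annotated R-peaks enter the TB tally. A plain-text
#' CSV with columns `sample,symbol` is accepted as an alternative carrier
#' for the same content.
#'
#' @param path Path to a `.atr`-style binary annotation file or a
#'   `sample,symbol` CSV.
#' @return A [beat_annotations()] tibble, sorted by sample.
#' @export
read_wfdb_annotations <- function(path) {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  if (grepl("\\.(csv|txt)$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, colClasses = c("integer", "character"))
    return(as_beat_annotations(df$sample, df$symbol))
  }
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) %% 2L == 1L) raw <- raw[-length(raw)]
  words <- readBin(raw, "integer",
    n = length(raw) %/% 2L, size = 2L,
    signed = FALSE, endian = "little"
  )
  positions <- integer(0)
  codes <- integer(0)
  t <- 0
  pending_skip <- 0
  i <- 1L
  while (i <= length(words)) {
    w <- words[[i]]
    code <- bitwShiftR(w, 10L)
    field <- bitwAnd(w, 1023L)
    if (w == 0L) break # EOF marker
    if (code == 59L) { # SKIP: 32-bit interval, high word first
      if (i + 2L > length(words)) {
        stop(sprintf(
          "truncated SKIP pseudo-annotation at byte offset %d in %s",
          (i - 1L) * 2L, path
        ), call. = FALSE)
      }
      hi <- words[[i + 1L]]
      lo <- words[[i + 2L]]
      pending_skip <- pending_skip + hi * 65536 + lo
      i <- i + 3L
      next
    }
    if (code == 63L) { # AUX: skip the string payload (padded to even length)
      i <- i + 1L + (field + field %% 2L) %/% 2L
      next
    }
    if (code %in% c(60L, 61L, 62L)) { # NUM / SUB / CHN modifiers
      i <- i + 1L
      next
    }
    if (code < 1L || code > 49L) {
      stop(sprintf(
        "unrecognized annotation code %d at byte offset %d in %s",
        code, (i - 1L) * 2L, path
      ), call. = FALSE)
    }
    t <- t + pending_skip + field
    pending_skip <- 0
    positions <- c(positions, t)
    codes <- c(codes, code)
    i <- i + 1L
  }
  keep <- codes %in% wfdb_beat_codes
  symbols <- unname(wfdb_code_symbol[as.character(codes[keep])])
  as_beat_annotations(positions[keep], symbols)
}

# Sorts, deduplicates, and builds the annotation tibble.
as_beat_annotations <- function(sample, symbol) {
  ord <- order(sample)
  sample <- as.integer(sample[ord])
  symbol <- symbol[ord]
  if (anyDuplicated(sample)) {
    keep <- !duplicated(sample)
    sample <- sample[keep]
    symbol <- symbol[keep]
  }
  keep <- is_beat_symbol(symbol)
  beat_annotations(sample[keep], symbol[keep])
}

#' Write beat annotations in the MIT `.atr` format
#'
#' Inverse of [read_wfdb_annotations()]; intervals longer than 1023 samples
#' are encoded with SKIP pseudo-annotations.
#'
#' @param annotations A [beat_annotations()] tibble.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_wfdb_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "beat_annotations"))
  sym_to_code <- stats::setNames(
    as.integer(names(wfdb_code_symbol)),
    unname(wfdb_code_symbol)
  )
  codes <- sym_to_code[annotations$symbol]
  if (anyNA(codes)) {
    stop("symbols without a WFDB code: ",
      paste(unique(annotations$symbol[is.na(codes)]), collapse = ", "),
      call. = FALSE
    )
  }
  words <- integer(0)
  prev <- 0
  for (i in seq_len(nrow(annotations))) {
    dt <- annotations$sample[[i]] - prev
    prev <- annotations$sample[[i]]
    if (dt > 1023) {
      words <- c(
        words, bitwShiftL(59L, 10L),
        dt %/% 65536, dt %% 65536,
        bitwShiftL(codes[[i]], 10L)
      )
    } else {
      words <- c(words, bitwOr(bitwShiftL(codes[[i]], 10L), as.integer(dt)))
    }
  }
  words <- c(words, 0L) # EOF
  con <- file(path, "wb")
  on.exit(close(con))
  for (w in words) {
    writeBin(as.raw(c(w %% 256L, w %/% 256L)), con)
  }
  invisible(path)
}

#' Read or write detections as CSV
#'
#' Detections interchange format: a CSV with columns
#' `record_id,sample_index` (0-based).
#'
#' @param detections A detections tibble as returned by the `detect_*()`
#'   functions (columns `record_id`, `algorithm`, `sample`).
#' @param path CSV file path.
#' @return `write_detections_csv()` returns `path` invisibly;
#'   `read_detections_csv()` returns a tibble with columns `record_id` and
#'   `sample`.
#' @export
write_detections_csv <- function(detections, path) {
  utils::write.csv(
    data.frame(
      record_id = detections$record_id,
      sample_index = detections$sample
    ),
    path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "integer"))
  tibble::tibble(record_id = df$record_id, sample = df$sample_index)
}
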