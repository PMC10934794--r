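#' Read a WFDB record
#'
#' Parses a WFDB header (`.hea`) and the signal file it names, and returns
#' the selected channel converted to physical units (mV). Signal storage
#' formats 212 (the MIT-BIH Arrhythmia Database dialect) and 16
#' (little-endian 16-bit) are supported.
#'
#' @param path Path to the record, with or without the `.hea` extension.
#' @param channel Zero-based channel index; the evaluation methodology uses
#'   the first channel (`0`).
#' @return An [ecg_record()].
#' @seealso [write_wfdb_record()], [read_wfdb_annotations()]
#' @export
read_wfdb_record <- function(path, channel = 0L) {
  hdr_path <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hdr_path)) {
    stop("WFDB header not found: ", hdr_path, call. = FALSE)
  }
  hdr <- parse_wfdb_header(hdr_path)
  channel <- as.integer(channel)
  if (hdr$nsig < 1L) {
    stop("header ", hdr_path, " declares no signals.", call. = FALSE)
  }
  if (channel < 0L || channel >= hdr$nsig) {
    stop("channel ", channel, " out of range: record has ", hdr$nsig,
      " signal(s).",
      call. = FALSE
    )
  }
  sig <- hdr$signals[channel + 1L, ]
  dat_path <- file.path(dirname(hdr_path), sig$file_name)
  if (!file.exists(dat_path)) {
    stop("WFDB signal file not found: ", dat_path, call. = FALSE)
  }
  adc <- switch(as.character(sig$format),
    "212" = read_dat_212(dat_path, hdr$nsig, hdr$nsamp),
    "16" = read_dat_16(dat_path, hdr$nsig, hdr$nsamp),
    stop("unsupported WFDB signal format: ", sig$format, call. = FALSE)
  )
  if (!is.na(hdr$nsamp) && hdr$nsamp > 0L && ncol(adc) != hdr$nsamp) {
    stop(
      "signal file ", dat_path, " holds ", ncol(adc),
      " samples/signal but the header declares ", hdr$nsamp, ".",
      call. = FALSE
    )
  }
  gain <- sig$gain
  if (is.na(gain) || gain == 0) gain <- 200
  baseline <- sig$baseline
  if (is.na(baseline)) baseline <- if (is.na(sig$adc_zero)) 0L else sig$adc_zero
  phys <- (adc[channel + 1L, ] - baseline) / gain
  ecg_record(phys,
    fs = hdr$fs, record_id = hdr$record_name,
    channel_index = channel,
    units = if (is.na(sig$units)) "mV" else sig$units,
    gain = gain, baseline = baseline
  )
}

#' Write an ECG record as a WFDB header/signal pair
#'
#' Emits `<record_id>.hea` plus `<record_id>.dat`. Physical samples are
#' quantized with the record's `gain`/`baseline`, so a read-back differs
#' from the original by at most one ADC step (`1/gain` mV). Format 16
#' (little-endian 16-bit) is written by default; format 212 is available
#' mainly to exercise the reader.
#'
#' @param record An [ecg_record()].
#' @param dir Output directory (created if missing).
#' @param format Signal storage format, `"16"` (default) or `"212"`.
#' @return Invisibly, the header path.
#' @export
write_wfdb_record <- function(record, dir, format = c("16", "212")) {
  stopifnot(is_ecg_record(record))
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  adc <- as.integer(round(record$samples * record$gain + record$baseline))
  lim <- if (format == "212") 2047L else 32767L
  if (any(adc > lim | adc < -lim - 1L)) {
    stop("samples exceed the ADC range of format ", format,
      " at gain ", record$gain, "; lower the gain.",
      call. = FALSE
    )
  }
  dat_name <- paste0(record$record_id, ".dat")
  hdr_path <- file.path(dir, paste0(record$record_id, ".hea"))
  adc_res <- if (format == "212") 12L else 16L
  hdr_lines <- c(
    sprintf("%s 1 %s %d", record$record_id, format_fs(record$fs), length(adc)),
    sprintf(
      "%s %s %g(%d)/%s %d %d %d 0 0 ECG",
      dat_name, format, record$gain, record$baseline, record$units,
      adc_res, record$baseline, adc[1L]
    )
  )
  writeLines(hdr_lines, hdr_path)
  dat_path <- file.path(dir, dat_name)
  if (format == "16") {
    write_dat_16(adc, dat_path)
  } else {
    write_dat_212(adc, dat_path)
  }
  invisible(hdr_path)
}

format_fs <- function(fs) {
  if (abs(fs - round(fs)) < 1e-9) sprintf("%d", as.integer(round(fs))) else sprintf("%g", fs)
}

# --- header -----------------------------------------------------------------

parse_wfdb_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("empty WFDB header: ", hdr_path, call. = FALSE)
  }
  rec <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  record_name <- sub("/.*$", "", rec[[1L]])
  nsig <- as.integer(rec[[2L]])
  fs <- if (length(rec) >= 3L) as.numeric(sub("/.*$", "", rec[[3L]])) else 250
  nsamp <- if (length(rec) >= 4L) as.integer(rec[[4L]]) else NA_integer_
  if (is.na(nsig) || nsig < 0L) {
    stop("malformed WFDB header record line in ", hdr_path, call. = FALSE)
  }
  n_avail <- length(lines) - 1L
  if (n_avail < nsig) {
    stop("header ", hdr_path, " declares ", nsig, " signals but lists ",
      n_avail, ".",
      call. = FALSE
    )
  }
  sig_rows <- lapply(seq_len(nsig), function(i) {
    parse_wfdb_signal_line(lines[[i + 1L]])
  })
  list(
    record_name = record_name, nsig = nsig, fs = fs, nsamp = nsamp,
    signals = do.call(rbind, sig_rows)
  )
}

parse_wfdb_signal_line <- function(line) {
  tok <- strsplit(trimws(line), "\\s+")[[1L]]
  file_name <- tok[[1L]]
  fmt_tok <- sub("[x:+].*$", "", tok[[2L]]) # strip samples/frame, skew, offset
  gain <- NA_real_
  baseline <- NA_integer_
  units <- NA_character_
  if (length(tok) >= 3L) {
    g <- tok[[3L]]
    if (grepl("/", g)) {
      units <- sub("^[^/]*/", "", g)
      g <- sub("/.*$", "", g)
    }
    if (grepl("\\(", g)) {
      baseline <- as.integer(sub("^.*\\(([-0-9]+)\\).*$", "\\1", g))
      g <- sub("\\(.*$", "", g)
    }
    gain <- suppressWarnings(as.numeric(g))
  }
  adc_zero <- if (length(tok) >= 5L) suppressWarnings(as.integer(tok[[5L]])) else NA_integer_
  data.frame(
    file_name = file_name, format = fmt_tok, gain = gain,
    baseline = baseline, units = units, adc_zero = adc_zero,
    stringsAsFactors = FALSE
  )
}

# --- signal codecs ----------------------------------------------------------
# Format 212: pairs of 12-bit two's-complement samples packed into 3 bytes.
# Format 16: 16-bit little-endian two's complement, signals interleaved.

read_dat_212 <- function(path, nsig, nsamp) {
  raw <- readBin(path, "raw", n = file.size(path))
  ntrip <- length(raw) %/% 3L
  if (ntrip == 0L) stop("signal file too short: ", path, call. = FALSE)
  b <- matrix(as.integer(raw[seq_len(3L * ntrip)]), nrow = 3L)
  s1 <- b[1L, ] + bitwShiftL(bitwAnd(b[2L, ], 0x0FL), 8L)
  s2 <- b[3L, ] + bitwShiftL(bitwShiftR(b[2L, ], 4L), 8L)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  flat <- as.vector(rbind(s1, s2))
  total <- if (!is.na(nsamp)) min(length(flat), nsamp * nsig) else length(flat)
  flat <- flat[seq_len(total)]
  matrix(flat, nrow = nsig)
}

write_dat_212 <- function(adc, path) {
  if (length(adc) %% 2L == 1L) adc <- c(adc, 0L) # pad to a full triplet
  u <- ifelse(adc < 0L, adc + 4096L, adc)
  s1 <- u[seq(1L, length(u), by = 2L)]
  s2 <- u[seq(2L, length(u), by = 2L)]
  b1 <- bitwAnd(s1, 0xFFL)
  b2 <- bitwOr(bitwShiftR(s1, 8L), bitwShiftL(bitwShiftR(s2, 8L), 4L))
  b3 <- bitwAnd(s2, 0xFFL)
  writeBin(as.raw(as.vector(rbind(b1, b2, b3))), path)
}

read_dat_16 <- function(path, nsig, nsamp) {
  n <- file.size(path) %/% 2L
  v <- readBin(path, "integer", n = n, size = 2L, signed = TRUE, endian = "little")
  total <- if (!is.na(nsamp)) min(length(v), nsamp * nsig) else length(v)
  matrix(v[seq_len(total)], nrow = nsig)
}

write_dat_16 <- function(adc, path) {
  writeBin(as.integer(adc), path, size = 2L, endian = "little")
}
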