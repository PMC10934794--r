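#' Morphology classes and WFDB annotation symbols
#'
#' The six most frequent beat morphologies in the MIT-BIH Arrhythmia
#' Database are tracked explicitly: N (normal), L (left bundle branch
#' block), R (right bundle branch block), V (premature ventricular), P
#' (paced, WFDB symbol `/`), and A (atrial premature). Every other WFDB
#' *beat* symbol maps to `OTHER`; non-beat annotations (rhythm changes,
#' signal-quality flags, ...) are not beats at all and are discarded by the
#' readers.
#'
#' @format `morphology_levels` is a character vector of the seven class
#'   labels in canonical order.
#' @export
morphology_levels <- c("N", "L", "R", "V", "P", "A", "OTHER")

# WFDB MIT annotation type codes <-> display symbols (standard table).
wfdb_code_symbol <- c(
  "1" = "N", "2" = "L", "3" = "R", "4" = "a", "5" = "V", "6" = "F",
  "7" = "J", "8" = "A", "9" = "S", "10" = "E", "11" = "j", "12" = "/",
  "13" = "Q", "14" = "~", "16" = "|", "18" = "s", "19" = "T", "20" = "*",
  "21" = "D", "22" = "\"", "23" = "=", "24" = "p", "25" = "B", "26" = "^",
  "27" = "t", "28" = "+", "29" = "u", "30" = "?", "31" = "!", "32" = "[",
  "33" = "]", "34" = "e", "35" = "n", "36" = "@", "37" = "x", "38" = "f",
  "39" = "(", "40" = ")", "41" = "r"
)

# Annotation type codes that denote heartbeats (QRS complexes).
wfdb_beat_codes <- c(1:13, 25L, 34L, 35L, 38L, 41L)

wfdb_beat_symbols <- unname(wfdb_code_symbol[as.character(wfdb_beat_codes)])

#' Map WFDB beat symbols to morphology classes
#'
#' Total mapping: the six tracked classes keep their identity (`/` becomes
#' `P`), every other beat symbol becomes `OTHER`. Symbols that are not beat
#' annotations produce `NA` so callers can drop them.
#'
#' @param symbol Character vector of WFDB annotation symbols.
#' @return Factor with levels [morphology_levels].
#' @examples
#' map_morphology(c("N", "/", "V", "f", "+"))
#' @export
map_morphology <- function(symbol) {
  out <- rep(NA_character_, length(symbol))
  is_beat <- symbol %in% wfdb_beat_symbols
  out[is_beat] <- "OTHER"
  direct <- c("N", "L", "R", "V", "A")
  out[symbol %in% direct] <- symbol[symbol %in% direct]
  out[symbol == "/"] <- "P"
  factor(out, levels = morphology_levels)
}

#' Is a WFDB symbol a beat annotation?
#' @param symbol Character vector of WFDB annotation symbols.
#' @return Logical vector.
#' @export
is_beat_symbol <- function(symbol) symbol %in% wfdb_beat_symbols

#' Construct a beat annotation table
#'
#' Reference R-peak positions with per-beat morphology labels, as a tibble
#' with columns `sample` (0-based sample index, strictly increasing),
#' `symbol` (WFDB display symbol) and `morphology` (factor over
#' [morphology_levels]).
#'
#' @param sample Integer vector of 0-based sample indices, strictly
#'   increasing.
#' @param symbol Character vector of WFDB beat symbols, one per position.
#' @return A tibble of class `beat_annotations`.
#' @examples
#' beat_annotations(c(10L, 400L), c("N", "/"))
#' @export
beat_annotations <- function(sample = integer(), symbol = character()) {
  sample <- as.integer(round(sample))
  symbol <- as.character(symbol)
  if (length(sample) != length(symbol)) {
    stop("`sample` and `symbol` must have the same length.", call. = FALSE)
  }
  if (length(sample) > 1L && any(diff(sample) <= 0L)) {
    stop("annotation positions must be strictly increasing.", call. = FALSE)
  }
  if (any(sample < 0L)) {
    stop("annotation positions must be non-negative sample indices.", call. = FALSE)
  }
  morph <- map_morphology(symbol)
  if (anyNA(morph) && length(symbol) > 0L) {
    bad <- unique(symbol[is.na(morph)])
    stop("not beat symbols: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(sample = sample, symbol = symbol, morphology = morph)
  class(out) <- c("beat_annotations", class(out))
  out
}
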