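# Small shared helpers: sequence arithmetic on plain character vectors and
# rounding conventions used across the calibration layer.

IUPAC_CHARS <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
                 "V", "H", "D", "B", "N")

# 15x15 lookup: do the base sets of two IUPAC codes intersect?
iupac_overlap_matrix <- function() {
  map <- Biostrings::IUPAC_CODE_MAP[IUPAC_CHARS]
  sets <- strsplit(unname(map), "")
  m <- matrix(FALSE, length(sets), length(sets),
              dimnames = list(IUPAC_CHARS, IUPAC_CHARS))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      m[i, j] <- length(intersect(sets[[i]], sets[[j]])) > 0L
    }
  }
  m
}

.iupac_overlap <- NULL

iupac_compatible <- function() {
  if (is.null(.iupac_overlap)) {
    utils::assignInMyNamespace(".iupac_overlap", iupac_overlap_matrix())
  }
  .iupac_overlap
}

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement for plain character vectors, honouring
#' IUPAC ambiguity codes.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AANT"))
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- character(length(x))
  ok <- !is.na(x) & nzchar(x)
  out[!ok] <- x[!ok]
  if (any(ok)) {
    out[ok] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[ok]))
    )
  }
  out
}

is_valid_dna <- function(x) {
  !is.na(x) & nzchar(x) & !grepl(paste0("[^", paste(IUPAC_CHARS, collapse = ""), "]"), x)
}

# Mismatches between an anchored IUPAC pattern and equally long sequence
# windows. `windows` is a character matrix [patternlen x nseq] of single
# characters; returns an integer vector of mismatch counts per sequence.
iupac_mismatch_counts <- function(pattern_chars, windows) {
  comp <- iupac_compatible()
  n <- ncol(windows)
  mism <- integer(n)
  for (i in seq_along(pattern_chars)) {
    p <- pattern_chars[i]
    row <- comp[p, ]
    obs <- windows[i, ]
    good <- row[match(obs, IUPAC_CHARS)]
    good[is.na(good)] <- FALSE
    mism <- mism + !good
  }
  mism
}

# Round half away from zero at `digits` decimals (base round() is
# half-to-even, which does not reproduce conventional reporting of
# midpoints such as (0.53 + 0.96) / 2 -> 0.75).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_ssr <- function(msg, class = "ssrgbs_error") {
  rlang::abort(msg, class = class)
}
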