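#' Read an SSR marker panel
#'
#' A marker panel is a tab-separated table with one row per SSR marker and
#' the fixed header `name`, `species`, `forward_primer`, `reverse_primer`,
#' `motif`, `motif_length`, `alpha`, `ce_offset`. `alpha` (the per-marker
#' first-allele frequency threshold used by [call_genotypes()]) and
#' `ce_offset` (the signed base-pair correction from digital amplicon
#' length to capillary-electrophoresis allele size) may be left blank until
#' the panel has been calibrated with [calibrate_markers()].
#'
#' @param path Path to the TSV file.
#' @return A tibble with one row per marker, classed `ssr_panel`.
#' @seealso [write_marker_panel()], [marker_panel()]
#' @export
read_marker_panel <- function(path) {
  if (!file.exists(path)) abort_ssr(paste0("marker panel file not found: ", path))
  df <- readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(),
    species = readr::col_character(),
    forward_primer = readr::col_character(),
    reverse_primer = readr::col_character(),
    motif = readr::col_character(),
    motif_length = readr::col_integer(),
    alpha = readr::col_double(),
    ce_offset = readr::col_integer()
  ))
  marker_panel(df)
}

#' Construct and validate a marker panel
#'
#' Validates primer alphabets, motif lengths and threshold ranges, and
#' rejects duplicated marker names. Problems are reported with the
#' offending row number (header = line 1 in the file representation).
#'
#' @param df Data frame with the marker-panel columns (see
#'   [read_marker_panel()]); `alpha` and `ce_offset` are optional and
#'   default to `NA`.
#' @return The validated panel as a tibble classed `ssr_panel`.
#' @export
marker_panel <- function(df) {
  df <- tibble::as_tibble(df)
  required <- c("name", "species", "forward_primer", "reverse_primer",
                "motif", "motif_length")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort_ssr(paste0("marker panel is missing columns: ",
                     paste(missing_cols, collapse = ", ")))
  }
  if (!"alpha" %in% names(df)) df$alpha <- NA_real_
  if (!"ce_offset" %in% names(df)) df$ce_offset <- NA_integer_
  df$motif_length <- as.integer(df$motif_length)
  df$ce_offset <- as.integer(df$ce_offset)

  dup <- df$name[duplicated(df$name)]
  if (length(dup) > 0) {
    abort_ssr(paste0("duplicated marker name(s): ",
                     paste(unique(dup), collapse = ", ")))
  }
  fail_row <- function(cond, what) {
    if (any(cond)) {
      # +1 converts the data-row index to the file line number
      abort_ssr(paste0(what, " in marker(s) ",
                       paste(df$name[cond], collapse = ", "),
                       " (line ", paste(which(cond) + 1L, collapse = ", "), ")"))
    }
  }
  fail_row(!is_valid_dna(df$forward_primer), "malformed forward primer (non-IUPAC)")
  fail_row(!is_valid_dna(df$reverse_primer), "malformed reverse primer (non-IUPAC)")
  fail_row(!is_valid_dna(df$motif), "malformed motif")
  fail_row(is.na(df$motif_length) | df$motif_length != nchar(df$motif),
           "motif_length does not equal nchar(motif)")
  fail_row(df$motif_length < 2L | df$motif_length > 5L,
           "motif_length outside [2, 5]")
  fail_row(!is.na(df$alpha) & (df$alpha <= 0 | df$alpha > 1),
           "alpha outside (0, 1]")
  df <- df[, c(required, "alpha", "ce_offset")]
  class(df) <- c("ssr_panel", class(df))
  df
}

#' Write a marker panel to TSV
#'
#' @param panel A marker panel tibble (see [marker_panel()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_panel <- function(panel, path) {
  panel <- marker_panel(panel)
  readr::write_tsv(panel, path, na = "")
  invisible(path)
}

#' Read a reference genotype table
#'
#' Reads a genotype matrix in CSV form: rows are varieties (first column
#' `variety`), remaining columns are markers, and each cell is an allele
#' pair `"a/b"` in base pairs (`"NA"` for a missing cell). This is the
#' format used for capillary-electrophoresis reference databases against
#' which sequencing-based calls are calibrated.
#'
#' @param path Path to the CSV file.
#' @return A long-format genotype table: a tibble with columns `variety`,
#'   `marker`, `allele_a`, `allele_b` (alleles sorted so
#'   `allele_a <= allele_b`; both `NA` for missing cells). Row order is
#'   variety-major, preserving the file's row and column order.
#' @seealso [write_genotype_table()]
#' @export
read_reference_genotypes <- function(path) {
  if (!file.exists(path)) abort_ssr(paste0("genotype file not found: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (names(df)[1] != "variety") {
    abort_ssr("first column of a genotype table must be 'variety'")
  }
  if (anyDuplicated(df$variety)) {
    abort_ssr(paste0("duplicated variety label(s): ",
                     paste(unique(df$variety[duplicated(df$variety)]), collapse = ", ")))
  }
  long <- tidyr::pivot_longer(df, -"variety", names_to = "marker",
                              values_to = "cell")
  parsed <- parse_genotype_cells(long$cell, long$variety, long$marker)
  out <- tibble::tibble(
    variety = long$variety,
    marker = long$marker,
    allele_a = parsed$a,
    allele_b = parsed$b
  )
  genotype_table(out)
}

# "a/b" -> sorted integer pair; "NA"/"" -> missing; anything else -> error
# with cell coordinates.
parse_genotype_cells <- function(cells, varieties, markers) {
  cells <- ifelse(is.na(cells) | cells == "" | toupper(cells) == "NA", NA, cells)
  a <- rep(NA_integer_, length(cells))
  b <- rep(NA_integer_, length(cells))
  idx <- which(!is.na(cells))
  if (length(idx) > 0) {
    parts <- stringr::str_split_fixed(cells[idx], "/", 2)
    av <- suppressWarnings(as.integer(parts[, 1]))
    bv <- suppressWarnings(as.integer(parts[, 2]))
    bad <- is.na(av) | is.na(bv) | av <= 0L | bv <= 0L |
      parts[, 1] != as.character(av) | parts[, 2] != as.character(bv)
    if (any(bad)) {
      j <- idx[which(bad)[1]]
      abort_ssr(paste0("non-integer genotype cell '", cells[j], "' at (",
                       varieties[j], ", ", markers[j], ")"))
    }
    a[idx] <- pmin(av, bv)
    b[idx] <- pmax(av, bv)
  }
  list(a = a, b = b)
}

#' Construct a long-format genotype table
#'
#' @param df Data frame with columns `variety`, `marker`, `allele_a`,
#'   `allele_b`. Allele pairs are put in non-decreasing order; a cell is
#'   missing when both alleles are `NA`.
#' @return A validated tibble.
#' @export
genotype_table <- function(df) {
  df <- tibble::as_tibble(df)[, c("variety", "marker", "allele_a", "allele_b")]
  df$allele_a <- as.integer(df$allele_a)
  df$allele_b <- as.integer(df$allele_b)
  half <- xor(is.na(df$allele_a), is.na(df$allele_b))
  if (any(half)) {
    abort_ssr("genotype cells must have both alleles or neither")
  }
  a <- pmin(df$allele_a, df$allele_b)
  b <- pmax(df$allele_a, df$allele_b)
  df$allele_a <- a
  df$allele_b <- b
  if (anyDuplicated(df[, c("variety", "marker")])) {
    abort_ssr("duplicated (variety, marker) cells in genotype table")
  }
  df
}

#' Write a genotype table to CSV
#'
#' Inverse of [read_reference_genotypes()]: pivots the long table to a
#' variety-by-marker CSV matrix with `"a/b"` cells and `"NA"` for missing
#' values. Variety and marker order follow first appearance in the long
#' table, so `read(write(x))` reproduces `x` exactly.
#'
#' @param table Long-format genotype table (see [genotype_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(table, path) {
  table <- genotype_table(table)
  wide <- table |>
    dplyr::mutate(cell = ifelse(is.na(.data$allele_a), NA_character_,
                                paste0(.data$allele_a, "/", .data$allele_b))) |>
    dplyr::select("variety", "marker", "cell") |>
    tidyr::pivot_wider(names_from = "marker", values_from = "cell")
  readr::write_csv(wide, path, na = "NA")
  invisible(path)
}
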