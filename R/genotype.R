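# Diploid genotype calling from allele profiles with the per-marker
# first-allele frequency threshold alpha: if the most common allele's
# frequency exceeds alpha the call is homozygous for that allele;
# otherwise it is heterozygous for the first and second alleles. The
# boundary is strict (f1 == alpha calls a heterozygote) and there is no
# epsilon.

#' Call one genotype from an allele profile
#'
#' @param profile One (variety, marker) cell of an [allele_profiles()]
#'   tibble, or any data frame with `rank`, `allele_length`, `freq`,
#'   `total_depth` rows for a single cell. Zero-depth cells may be passed
#'   as a zero-row data frame.
#' @param alpha Frequency threshold in (0, 1].
#' @param min_depth Cells with fewer reads get status `"low_depth"`.
#' @return One-row tibble: `allele_a`, `allele_b` (GBS scale; `NA` unless
#'   called), `status` (`"called"`, `"low_depth"`, `"no_reads"`),
#'   `total_depth`, `first_allele_freq`.
#' @export
call_genotype <- function(profile, alpha, min_depth = 10) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha > 1) {
    abort_ssr("alpha must be a single value in (0, 1]")
  }
  profile <- dplyr::arrange(tibble::as_tibble(profile), .data$rank)
  depth <- if (nrow(profile) == 0) 0L else profile$total_depth[1]
  f1 <- if (nrow(profile) == 0) NA_real_ else profile$freq[1]
  empty <- function(status) {
    tibble::tibble(allele_a = NA_integer_, allele_b = NA_integer_,
                   status = status, total_depth = as.integer(depth),
                   first_allele_freq = f1)
  }
  if (depth == 0L) return(empty("no_reads"))
  if (depth < min_depth) return(empty("low_depth"))
  if (f1 > alpha) {
    a <- profile$allele_length[1]
    b <- a
  } else {
    if (nrow(profile) < 2) return(empty("low_depth")) # f1 <= alpha needs a 2nd allele
    a <- min(profile$allele_length[1:2])
    b <- max(profile$allele_length[1:2])
  }
  tibble::tibble(allele_a = as.integer(a), allele_b = as.integer(b),
                 status = "called", total_depth = as.integer(depth),
                 first_allele_freq = f1)
}

#' Call genotypes for every (variety, marker) cell
#'
#' Applies [call_genotype()] to each cell of an allele-profile table,
#' taking alpha per marker from the panel (or a single override).
#'
#' @param profiles Tibble from [allele_profiles()].
#' @param panel Marker panel with the `alpha` column set (ignored when
#'   `alpha` is given).
#' @param alpha Optional single threshold applied to every marker.
#' @param min_depth Per-cell minimum read depth.
#' @return Tibble `variety`, `marker`, `allele_a`, `allele_b`, `status`,
#'   `total_depth`, `first_allele_freq`, classed `ssr_calls`. Cells with
#'   status other than `"called"` have `NA` alleles.
#' @export
call_genotypes <- function(profiles, panel = NULL, alpha = NULL,
                           min_depth = 10) {
  if (is.null(alpha)) {
    if (is.null(panel)) abort_ssr("either a calibrated panel or alpha is required")
    panel <- marker_panel(panel)
    markers <- unique(profiles$marker)
    unset <- markers[is.na(panel$alpha[match(markers, panel$name)])]
    if (length(unset) > 0) {
      abort_ssr(paste0("alpha is not set for marker(s): ",
                       paste(unset, collapse = ", ")))
    }
    alpha_of <- setNames(panel$alpha, panel$name)
  } else {
    alpha_of <- NULL
  }
  out <- profiles |>
    dplyr::group_by(.data$variety, .data$marker) |>
    dplyr::group_modify(function(df, key) {
      a <- if (is.null(alpha_of)) alpha else unname(alpha_of[[key$marker]])
      call_genotype(df, alpha = a, min_depth = min_depth)
    }) |>
    dplyr::ungroup()
  class(out) <- c("ssr_calls", class(out))
  out
}

#' Shift called alleles onto the capillary-electrophoresis scale
#'
#' Adds each marker's `ce_offset` (defined as CE size minus GBS digital
#' length) to both alleles, converting digital lengths to the CE scale.
#' Apply with negated offsets to go the other way (see
#' [invert_offsets()]).
#'
#' @param table Genotype table or call tibble with `marker`, `allele_a`,
#'   `allele_b` columns.
#' @param panel Marker panel with `ce_offset` set for every marker used.
#' @return `table` with shifted alleles; missing cells are preserved.
#' @export
apply_size_offset <- function(table, panel) {
  panel <- marker_panel(panel)
  offs <- panel$ce_offset[match(table$marker, panel$name)]
  unset <- unique(table$marker[is.na(offs)])
  if (length(unset) > 0) {
    abort_ssr(paste0("ce_offset is not set for marker(s): ",
                     paste(unset, collapse = ", ")))
  }
  table$allele_a <- as.integer(table$allele_a + offs)
  table$allele_b <- as.integer(table$allele_b + offs)
  table
}

#' Negate the CE offsets of a panel
#'
#' Convenience for converting CE-scale tables back to the digital (GBS)
#' scale with [apply_size_offset()].
#'
#' @param panel Marker panel.
#' @return The panel with `ce_offset` negated.
#' @export
invert_offsets <- function(panel) {
  panel$ce_offset <- -panel$ce_offset
  panel
}

#' Reduce calls to a genotype table
#'
#' Keeps called cells and blanks the rest, yielding the long genotype
#' format of [genotype_table()] (suitable for [write_genotype_table()]).
#'
#' @param calls Tibble from [call_genotypes()].
#' @return Long genotype table with `NA` alleles for uncalled cells.
#' @export
as_genotype_table <- function(calls) {
  out <- calls |>
    dplyr::mutate(
      allele_a = ifelse(.data$status == "called", .data$allele_a, NA_integer_),
      allele_b = ifelse(.data$status == "called", .data$allele_b, NA_integer_)
    ) |>
    dplyr::select("variety", "marker", "allele_a", "allele_b")
  genotype_table(out)
}

#' Per-cell QC table
#'
#' A wide per-cell quality-control summary mirroring how allele
#' frequencies are inspected by eye: depth, the four top allele
#' frequencies and the call status. The third and fourth alleles are not
#' used for calling but reveal stutter bands and other artifacts.
#'
#' @param profiles Tibble from [allele_profiles()].
#' @param calls Tibble from [call_genotypes()] on the same profiles.
#' @return Tibble `variety`, `marker`, `total_depth`, `f1`..`f4`,
#'   `status`.
#' @export
genotype_qc <- function(profiles, calls) {
  freqs <- profiles |>
    dplyr::filter(.data$rank <= 4) |>
    dplyr::select("variety", "marker", "rank", "freq") |>
    tidyr::pivot_wider(names_from = "rank", values_from = "freq",
                       names_prefix = "f")
  for (col in paste0("f", 1:4)) {
    if (!col %in% names(freqs)) freqs[[col]] <- NA_real_
  }
  calls |>
    dplyr::select("variety", "marker", "total_depth", "status") |>
    dplyr::left_join(freqs[, c("variety", "marker", paste0("f", 1:4))],
                     by = c("variety", "marker")) |>
    dplyr::relocate("status", .after = dplyr::last_col())
}
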