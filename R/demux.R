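# Primer demultiplexing and digital allele counting. An allele is the
# full merged-read length in bp (both primers included): a "digital"
# fragment size that can be compared to capillary electrophoresis through
# a single per-marker offset.

#' Assign merged reads to markers by primer sequence
#'
#' A read is assigned to marker M when it starts with M's forward primer
#' and ends with the reverse complement of M's reverse primer, each with
#' at most `max_mismatches` substitutions (IUPAC codes in primers match
#' their base sets; no indels). Reads failing in the given orientation are
#' tested reverse-complemented. Reads matching no marker are `unassigned`;
#' reads matching more than one are `ambiguous` and not assigned.
#'
#' @param reads Character vector of merged read sequences, or the `reads`
#'   tibble from [merge_fastq()].
#' @param panel Marker panel (see [marker_panel()]).
#' @param max_mismatches Maximum substitutions tolerated per primer.
#' @param both_orientations Also test the reverse-complemented read.
#' @return A tibble with one row per read: `seq`, `length`, `marker`
#'   (`NA` when not assigned) and `assignment` (`"assigned"`,
#'   `"unassigned"` or `"ambiguous"`).
#' @export
assign_markers <- function(reads, panel, max_mismatches = 0,
                           both_orientations = TRUE) {
  if (is.data.frame(reads)) reads <- reads$seq
  panel <- marker_panel(panel)
  if (anyDuplicated(paste(panel$forward_primer, panel$reverse_primer))) {
    abort_ssr("panel primer pairs must be pairwise distinct")
  }
  n <- length(reads)
  out <- tibble::tibble(seq = reads, length = nchar(reads),
                        marker = NA_character_,
                        assignment = "unassigned")
  if (n == 0 || nrow(panel) == 0) return(out)

  # Work on distinct sequences only; amplicon reads are highly duplicated.
  useq <- unique(reads)
  hits <- matrix(FALSE, length(useq), nrow(panel))
  orientations <- list(useq)
  if (both_orientations) orientations <- c(orientations, list(revcomp(useq)))
  for (ori in orientations) {
    for (m in seq_len(nrow(panel))) {
      hits[, m] <- hits[, m] |
        primer_pair_match(ori, panel$forward_primer[m],
                          panel$reverse_primer[m], max_mismatches)
    }
  }
  nhit <- rowSums(hits)
  umarker <- rep(NA_character_, length(useq))
  umarker[nhit == 1L] <- panel$name[apply(hits[nhit == 1L, , drop = FALSE], 1,
                                          which)]
  ustatus <- ifelse(nhit == 0L, "unassigned",
                    ifelse(nhit == 1L, "assigned", "ambiguous"))
  idx <- match(reads, useq)
  out$marker <- umarker[idx]
  out$assignment <- ustatus[idx]
  out
}

# Anchored prefix/suffix primer match with <= max_mismatches substitutions
# each; vectorised over sequences.
primer_pair_match <- function(seqs, fwd, rev, max_mismatches) {
  flen <- nchar(fwd)
  rrc <- revcomp(rev)
  rlen <- nchar(rrc)
  ok <- nchar(seqs) >= flen + rlen
  res <- logical(length(seqs))
  if (!any(ok)) return(res)
  sub <- seqs[ok]
  pre <- substr(sub, 1L, flen)
  suf <- substr(sub, nchar(sub) - rlen + 1L, nchar(sub))
  fchars <- strsplit(fwd, "")[[1]]
  rchars <- strsplit(rrc, "")[[1]]
  pre_m <- matrix(unlist(strsplit(pre, ""), use.names = FALSE), nrow = flen)
  suf_m <- matrix(unlist(strsplit(suf, ""), use.names = FALSE), nrow = rlen)
  res[ok] <- iupac_mismatch_counts(fchars, pre_m) <= max_mismatches &
    iupac_mismatch_counts(rchars, suf_m) <= max_mismatches
  res
}

#' Count reads per allele length
#'
#' Accumulates marker-assigned reads of one variety into a digital allele
#' count table: reads per full merged length, per marker.
#'
#' @param assigned Tibble from [assign_markers()] (rows with
#'   `assignment != "assigned"` are ignored), or a tibble with columns
#'   `marker` and `length`.
#' @param variety Variety label recorded in the output.
#' @param markers Optional character vector of marker names; markers with
#'   zero reads are then included with `total_depth` 0 (no count rows).
#' @return A tibble with columns `variety`, `marker`, `allele_length`,
#'   `count`, plus an attribute-free summary obtainable with
#'   [marker_depths()].
#' @export
count_alleles <- function(assigned, variety, markers = NULL) {
  if ("assignment" %in% names(assigned)) {
    assigned <- dplyr::filter(assigned, .data$assignment == "assigned")
  }
  counts <- assigned |>
    dplyr::count(.data$marker, .data$length, name = "n_reads") |>
    dplyr::transmute(variety = .env$variety, marker = .data$marker,
                     allele_length = as.integer(.data$length),
                     count = as.integer(.data$n_reads))
  if (!is.null(markers)) {
    missing <- setdiff(markers, counts$marker)
    counts <- counts[counts$marker %in% markers, , drop = FALSE]
    attr(counts, "zero_depth_markers") <- missing
  }
  dplyr::arrange(counts, .data$marker, .data$allele_length)
}

#' Per-(variety, marker) read depth
#'
#' @param counts Allele count tibble from [count_alleles()] (any number of
#'   varieties).
#' @return Tibble `variety`, `marker`, `total_depth`.
#' @export
marker_depths <- function(counts) {
  counts |>
    dplyr::group_by(.data$variety, .data$marker) |>
    dplyr::summarise(total_depth = sum(.data$count), .groups = "drop")
}

#' Average read depth per marker across varieties
#'
#' @param counts Allele count tibble covering one or more varieties.
#' @param varieties Optional vector of all varieties profiled; varieties
#'   with zero reads for a marker then contribute 0 to its mean.
#' @return Tibble `marker`, `avg_depth`.
#' @export
average_depth <- function(counts, varieties = NULL) {
  depths <- marker_depths(counts)
  if (nrow(depths) == 0) abort_ssr("average_depth() needs at least one variety")
  varieties <- varieties %||% unique(depths$variety)
  depths |>
    tidyr::complete(variety = varieties, marker = unique(depths$marker),
                    fill = list(total_depth = 0L)) |>
    dplyr::group_by(.data$marker) |>
    dplyr::summarise(avg_depth = mean(.data$total_depth), .groups = "drop")
}

#' Top-k allele profile
#'
#' Reduces an allele count table to the `k` most common allele lengths per
#' (variety, marker), with frequencies over the *total* read depth of that
#' cell (not the top-k sum). Count ties are broken toward the smaller
#' allele length.
#'
#' @param counts Allele count tibble from [count_alleles()].
#' @param k Number of alleles retained (default 4).
#' @return Tibble `variety`, `marker`, `total_depth`, `rank`,
#'   `allele_length`, `count`, `freq`, classed `ssr_profiles`.
#' @export
allele_profiles <- function(counts, k = 4) {
  out <- counts |>
    dplyr::group_by(.data$variety, .data$marker) |>
    dplyr::mutate(total_depth = sum(.data$count)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$allele_length,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = k) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  freq = .data$count / .data$total_depth) |>
    dplyr::ungroup() |>
    dplyr::select("variety", "marker", "total_depth", "rank",
                  "allele_length", "count", "freq")
  class(out) <- c("ssr_profiles", class(out))
  out
}
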