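#' Run the SSR-GBS pipeline over a directory of paired FASTQ files
#'
#' Chains the four pipeline stages: merge read pairs, demultiplex merged
#' reads by primer, count digital allele lengths, and (when thresholds
#' are available) call genotypes. Input files are discovered as
#' `<variety>_R1.fastq[.gz]` / `<variety>_R2.fastq[.gz]` pairs.
#'
#' @param reads_dir Directory containing the paired FASTQ files.
#' @param panel Marker panel (tibble or TSV path).
#' @param alpha Optional single threshold overriding the panel's
#'   per-marker `alpha`.
#' @param min_depth Per-cell depth below which calls get status
#'   `low_depth`.
#' @param max_mismatches Substitutions tolerated per primer during
#'   demultiplexing.
#' @param call Set `FALSE` to stop after counting (e.g. before
#'   calibration, when no alpha exists yet).
#' @param merge_args List of extra arguments for [merge_read_pair()].
#' @return List with `merge_stats`, `demux_stats`, `counts`, `profiles`
#'   and (when calling) `calls` and `genotypes`.
#' @export
run_ssr_pipeline <- function(reads_dir, panel, alpha = NULL, min_depth = 10,
                             max_mismatches = 0, call = TRUE,
                             merge_args = list()) {
  if (is.character(panel) && length(panel) == 1) panel <- read_marker_panel(panel)
  panel <- marker_panel(panel)
  pairs <- find_fastq_pairs(reads_dir)
  if (nrow(pairs) == 0) abort_ssr(paste0("no *_R1/*_R2 FASTQ pairs found in ", reads_dir))

  merge_stats <- list()
  demux_stats <- list()
  counts <- list()
  for (i in seq_len(nrow(pairs))) {
    v <- pairs$variety[i]
    merged <- do.call(merge_fastq,
                      c(list(pairs$r1[i], pairs$r2[i], out_path = NULL),
                        merge_args))
    merge_stats[[v]] <- dplyr::mutate(merged$stats, variety = v,
                                      .before = 1)
    assigned <- assign_markers(merged$reads, panel,
                               max_mismatches = max_mismatches)
    demux_stats[[v]] <- assigned |>
      dplyr::count(.data$assignment) |>
      tidyr::pivot_wider(names_from = "assignment", values_from = "n",
                         values_fill = 0L) |>
      dplyr::mutate(variety = v, .before = 1)
    counts[[v]] <- count_alleles(assigned, v, markers = panel$name)
  }
  counts <- dplyr::bind_rows(counts)
  profiles <- allele_profiles(counts)
  out <- list(
    merge_stats = dplyr::bind_rows(merge_stats),
    demux_stats = dplyr::bind_rows(demux_stats),
    counts = counts,
    profiles = profiles,
    avg_depth = average_depth(counts, varieties = pairs$variety)
  )
  if (call) {
    calls <- call_genotypes(profiles, panel = panel, alpha = alpha,
                            min_depth = min_depth)
    out$calls <- calls
    out$genotypes <- as_genotype_table(calls)
    out$qc <- genotype_qc(profiles, calls)
  }
  out
}

find_fastq_pairs <- function(dir) {
  r1 <- sort(list.files(dir, pattern = "_R1\\.fastq(\\.gz)?$",
                        full.names = TRUE))
  varieties <- sub("_R1\\.fastq(\\.gz)?$", "", basename(r1))
  r2 <- file.path(dirname(r1), sub("_R1\\.fastq", "_R2.fastq", basename(r1)))
  missing <- !file.exists(r2)
  if (any(missing)) {
    abort_ssr(paste0("missing R2 mate for: ",
                     paste(basename(r1[missing]), collapse = ", ")))
  }
  tibble::tibble(variety = varieties, r1 = r1, r2 = r2)
}

#' Write the long allele count table
#'
#' @param counts Tibble from [count_alleles()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read a long allele count table
#'
#' @param path TSV with columns `variety`, `marker`, `allele_length`,
#'   `count`.
#' @return Tibble in [count_alleles()] format.
#' @export
read_allele_counts <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    variety = readr::col_character(),
    marker = readr::col_character(),
    allele_length = readr::col_integer(),
    count = readr::col_integer()
  ))
}
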