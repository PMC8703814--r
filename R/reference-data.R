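# Bundled reference tables from a published SSR database covering 116
# varieties (43 apple, 29 pear, 44 tea) genotyped in parallel by
# capillary electrophoresis and by amplicon sequencing with 37 markers.
# They document the per-marker sequencing depths, CE size differences and
# suitability outcomes, the calibrated alpha intervals of the 27 retained
# markers, and the CE locus statistics - enough to exercise the
# calibration and statistics layers at desk scale.

ssr_extdata <- function(file) {
  path <- system.file("extdata", file, package = "ssrgbs")
  if (path == "") abort_ssr(paste0("bundled file not found: ", file))
  path
}

#' Marker survey of the bundled apple/pear/tea panel
#'
#' Per-marker average sequencing depth in two replicate runs, the signed
#' size difference of sequenced alleles from CE sizes, and the observed
#' outcome: `comparable`, `stutter_errors`, `allele_dropout`,
#' `low_depth_variety` (genotype undeterminable in specific varieties) or
#' `low_depth` (whole marker under-sequenced), with affected varieties
#' where recorded.
#'
#' @return Tibble with 37 rows.
#' @export
marker_survey <- function() {
  readr::read_tsv(ssr_extdata("marker_survey.tsv"), col_types = readr::cols(
    marker = readr::col_character(), species = readr::col_character(),
    avg_depth = readr::col_integer(),
    avg_depth_replicate = readr::col_integer(),
    ce_size_diff = readr::col_integer(), result = readr::col_character(),
    affected_varieties = readr::col_character()
  ))
}

#' Calibrated alpha intervals of the bundled panel
#'
#' For each of the 27 markers retained for automated genotyping: the
#' feasible threshold interval (`alpha_min`, `alpha_max`), the reported
#' optimum, and the between-replicate correlation of first-allele
#' frequencies.
#'
#' @return Tibble with 27 rows.
#' @export
alpha_reference <- function() {
  readr::read_tsv(ssr_extdata("alpha_reference.tsv"), col_types = readr::cols(
    marker = readr::col_character(), species = readr::col_character(),
    .default = readr::col_double()
  ))
}

#' CE locus statistics of the bundled panel
#'
#' Allele counts, observed/expected heterozygosity and PIC per marker as
#' determined by capillary electrophoresis, with the sequencing
#' suitability flag.
#'
#' @return Tibble with 37 rows.
#' @export
locus_stats_reference <- function() {
  readr::read_tsv(ssr_extdata("locus_stats.tsv"), col_types = readr::cols(
    marker = readr::col_character(), species = readr::col_character(),
    n_alleles = readr::col_integer(), ho = readr::col_double(),
    he = readr::col_double(), pic = readr::col_double(),
    gbs_suitable = readr::col_logical()
  ))
}

#' Apply the marker suitability rules to a survey table
#'
#' Reproduces database construction from the survey annotations: a marker
#' is retained when its average depth passes `depth_threshold` and its
#' result is `comparable` (no stutter errors, no allele dropout, no
#' varieties with undeterminable genotypes).
#'
#' @param survey Tibble from [marker_survey()].
#' @param depth_threshold Average-depth cutoff in reads.
#' @return The survey with logical columns `depth_pass` and `suitable`.
#' @export
survey_suitability <- function(survey = marker_survey(),
                               depth_threshold = 50) {
  survey |>
    dplyr::mutate(
      depth_pass = .data$avg_depth >= depth_threshold,
      suitable = .data$depth_pass & .data$result == "comparable"
    )
}
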