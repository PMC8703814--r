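# Calibration of the genotyping layer against a capillary-electrophoresis
# (CE) reference database. Three per-marker quantities are estimated:
#
# * the feasible interval of the frequency threshold alpha, i.e. the set
#   of thresholds under which automated calls reproduce the reference
#   exactly for every calibration variety, and its midpoint optimum;
# * the signed size offset between CE allele sizes and digital (GBS)
#   amplicon lengths (ce_offset = CE - GBS);
# * allele dropout: reference alleles invisible even among the top-4
#   sequenced alleles, the signature of a null allele.
#
# Markers are then classified (suitable / low_depth / dropout /
# stutter_error / discordant) in that order of precedence.

#' Estimate the feasible alpha interval for one marker
#'
#' Under the calling rule (first-allele frequency `f1 > alpha` calls a
#' homozygote, `f1 <= alpha` a heterozygote), a reference-heterozygous
#' variety is reproduced by every `alpha >= f1` and a reference-homozygous
#' variety by every `alpha < f1`. The feasible set over all calibration
#' varieties is therefore `[max het f1, min hom f1)`; the reported
#' interval is `alpha_min = max het f1` (0 when no heterozygotes),
#' `alpha_max = min hom f1` (1 when no homozygotes), and the optimum is
#' their midpoint rounded half-up to 2 decimals. The interval is only
#' valid when the allele identities agree: the top allele (homozygotes) or
#' top two alleles (heterozygotes) must equal the reference alleles after
#' offset correction for every variety; otherwise no threshold can
#' reconcile the two methods and the marker is infeasible.
#'
#' @param profiles [allele_profiles()] rows for a single marker across the
#'   calibration varieties.
#' @param reference CE-scale genotype table (long format); only rows for
#'   `marker` are used. Varieties with missing reference cells are
#'   skipped.
#' @param offset Signed CE-minus-GBS size offset for this marker.
#' @param min_depth Varieties with fewer reads are excluded from
#'   calibration.
#' @param motif_length Optional motif length in bp, used to label
#'   infeasibility caused by one-motif-unit artifacts as `"stutter"`.
#' @param marker Marker name (defaults to the single marker present in
#'   `profiles`).
#' @return One-row tibble: `marker`, `alpha_min`, `alpha_opt`,
#'   `alpha_max`, `feasible`, `reason` (`"ok"`, `"no_varieties"`,
#'   `"allele_mismatch"`, `"stutter"`, `"interval_empty"`),
#'   `n_calibration`, and a `mismatches` list column detailing discordant
#'   varieties.
#' @export
estimate_alpha_range <- function(profiles, reference, offset, min_depth = 10,
                                 motif_length = NULL, marker = NULL) {
  marker <- marker %||% unique(profiles$marker)
  if (length(marker) != 1) abort_ssr("profiles must cover exactly one marker")
  prof <- dplyr::filter(profiles, .data$marker == .env$marker,
                        .data$total_depth >= min_depth)
  ref <- dplyr::filter(reference, .data$marker == .env$marker,
                       !is.na(.data$allele_a))

  infeasible <- function(reason, mism = empty_mismatch(), n = 0L) {
    tibble::tibble(marker = marker, alpha_min = NA_real_, alpha_opt = NA_real_,
                   alpha_max = NA_real_, feasible = FALSE, reason = reason,
                   n_calibration = n, mismatches = list(mism))
  }
  varieties <- intersect(unique(prof$variety), ref$variety)
  if (length(varieties) == 0) return(infeasible("no_varieties"))

  het_f1 <- numeric(0)
  hom_f1 <- numeric(0)
  mism <- list()
  for (v in varieties) {
    p <- prof[prof$variety == v, ]
    p <- p[order(p$rank), ]
    r <- ref[ref$variety == v, ]
    expected <- sort(c(r$allele_a, r$allele_b)) - offset
    f1 <- p$freq[1]
    if (r$allele_a == r$allele_b) {
      observed <- p$allele_length[1]
      ok <- observed == expected[1]
      if (ok) hom_f1 <- c(hom_f1, f1)
    } else {
      observed <- if (nrow(p) >= 2) sort(p$allele_length[1:2]) else p$allele_length[1]
      ok <- length(observed) == 2 && all(observed == expected)
      if (ok) het_f1 <- c(het_f1, f1)
    }
    if (!ok) {
      offending <- setdiff(observed, expected)
      mism[[length(mism) + 1L]] <- tibble::tibble(
        variety = v,
        observed = paste(observed, collapse = "/"),
        expected = paste(expected, collapse = "/"),
        top1 = p$allele_length[1],
        offending = list(offending)
      )
    }
  }
  if (length(mism) > 0) {
    mism_df <- dplyr::bind_rows(mism)
    reason <- "allele_mismatch"
    if (!is.null(motif_length)) {
      offending <- unlist(mism_df$offending)
      top1 <- rep(mism_df$top1, lengths(mism_df$offending))
      if (length(offending) > 0 &&
          all(abs(offending - top1) == motif_length)) {
        reason <- "stutter"
      }
    }
    return(infeasible(reason, mism_df, length(varieties)))
  }
  alpha_min <- if (length(het_f1) > 0) max(het_f1) else 0
  alpha_max <- if (length(hom_f1) > 0) min(hom_f1) else 1
  if (alpha_min >= alpha_max) {
    return(infeasible("interval_empty", n = length(varieties)))
  }
  tibble::tibble(
    marker = marker,
    alpha_min = alpha_min,
    alpha_opt = alpha_midpoint(alpha_min, alpha_max),
    alpha_max = alpha_max,
    feasible = TRUE, reason = "ok",
    n_calibration = length(varieties),
    mismatches = list(empty_mismatch())
  )
}

empty_mismatch <- function() {
  tibble::tibble(variety = character(), observed = character(),
                 expected = character(), top1 = integer(),
                 offending = list())
}

#' Midpoint optimum of an alpha interval
#'
#' The optimum threshold is the interval midpoint, rounded half away from
#' zero at two decimals (so 0.745 reports as 0.75).
#'
#' @param alpha_min,alpha_max Interval endpoints.
#' @return Numeric vector of midpoints.
#' @export
alpha_midpoint <- function(alpha_min, alpha_max) {
  round_half_up((alpha_min + alpha_max) / 2, 2)
}

#' Estimate CE-GBS size offsets
#'
#' For every variety with both a (GBS-scale) called genotype and a CE
#' reference genotype, alleles are paired positionally after sorting
#' within the variety, giving two signed differences `CE - GBS`. The
#' marker's offset is the mode of all differences, ties broken toward the
#' smaller absolute offset (then the smaller value).
#'
#' @param calls GBS-scale genotype table or [call_genotypes()] output.
#' @param reference CE-scale genotype table.
#' @return Tibble `marker`, `ce_offset`, `n_varieties`, with a per-pair
#'   `report` attribute (`marker`, `variety`, `diff_a`, `diff_b`).
#' @export
estimate_size_offsets <- function(calls, reference) {
  joined <- dplyr::inner_join(
    dplyr::filter(tibble::as_tibble(calls), !is.na(.data$allele_a)),
    dplyr::filter(tibble::as_tibble(reference), !is.na(.data$allele_a)),
    by = c("variety", "marker"), suffix = c("_gbs", "_ce")
  )
  report <- joined |>
    dplyr::transmute(
      marker = .data$marker, variety = .data$variety,
      diff_a = .data$allele_a_ce - .data$allele_a_gbs,
      diff_b = .data$allele_b_ce - .data$allele_b_gbs
    )
  out <- report |>
    tidyr::pivot_longer(c("diff_a", "diff_b"), values_to = "diff") |>
    dplyr::group_by(.data$marker) |>
    dplyr::summarise(ce_offset = modal_offset(.data$diff),
                     n_varieties = dplyr::n() / 2L, .groups = "drop")
  attr(out, "report") <- report
  out
}

# Mode with deterministic ties: most frequent, then smallest |x|, then
# smallest x.
modal_offset <- function(x) {
  tab <- table(x)
  vals <- as.integer(names(tab))
  cnt <- as.integer(tab)
  ord <- order(-cnt, abs(vals), vals)
  vals[ord[1]]
}

#' Detect allele dropout against a CE reference
#'
#' A reference allele is flagged as dropped for a variety when, after
#' offset correction, no allele of the variety's top-4 sequenced profile
#' matches it. Varieties below `min_depth` are skipped (absence of reads
#' is not evidence of a null allele).
#'
#' @param profiles [allele_profiles()] tibble.
#' @param reference CE-scale genotype table.
#' @param offsets Either a marker panel with `ce_offset` set or a tibble
#'   `marker`, `ce_offset` (e.g. from [estimate_size_offsets()]).
#' @param min_depth Minimum per-variety depth for assessment.
#' @return Tibble `marker`, `variety`, `ce_allele` (one row per dropped
#'   allele).
#' @export
detect_allele_dropout <- function(profiles, reference, offsets,
                                  min_depth = 10) {
  if ("name" %in% names(offsets)) {
    offsets <- tibble::tibble(marker = offsets$name,
                              ce_offset = offsets$ce_offset)
  }
  top4 <- profiles |>
    dplyr::filter(.data$rank <= 4, .data$total_depth >= min_depth) |>
    dplyr::group_by(.data$variety, .data$marker) |>
    dplyr::summarise(lengths = list(.data$allele_length), .groups = "drop")
  ref <- reference |>
    dplyr::filter(!is.na(.data$allele_a)) |>
    dplyr::inner_join(top4, by = c("variety", "marker")) |>
    dplyr::inner_join(offsets, by = "marker")
  if (nrow(ref) == 0) {
    return(tibble::tibble(marker = character(), variety = character(),
                          ce_allele = integer()))
  }
  rows <- purrr::pmap(
    list(ref$marker, ref$variety, ref$allele_a, ref$allele_b,
         ref$lengths, ref$ce_offset),
    function(marker, variety, a, b, lens, off) {
      ce <- unique(c(a, b))
      dropped <- ce[!(ce - off) %in% lens]
      if (length(dropped) == 0) return(NULL)
      tibble::tibble(marker = marker, variety = variety,
                     ce_allele = as.integer(dropped))
    }
  )
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(marker = character(), variety = character(),
                          ce_allele = integer())
  }
  dplyr::arrange(out, .data$marker, .data$variety, .data$ce_allele)
}

#' Classify marker suitability
#'
#' Deterministic precedence: average depth below `depth_threshold` makes a
#' marker `"low_depth"`; otherwise any allele dropout makes it
#' `"dropout"`; otherwise an infeasible alpha interval makes it
#' `"stutter_error"` (when the discordance is explained by one-motif-unit
#' artifacts) or `"discordant"`; otherwise it is `"suitable"`.
#'
#' @param avg_depth Mean reads per variety for the marker.
#' @param n_dropout Number of dropped (variety, allele) pairs.
#' @param feasible Logical from [estimate_alpha_range()].
#' @param reason Infeasibility reason from [estimate_alpha_range()].
#' @param depth_threshold Average-depth cutoff (reads).
#' @return One of `"suitable"`, `"low_depth"`, `"dropout"`,
#'   `"stutter_error"`, `"discordant"`.
#' @export
classify_marker <- function(avg_depth, n_dropout, feasible, reason = "ok",
                            depth_threshold = 50) {
  if (avg_depth < depth_threshold) return("low_depth")
  if (n_dropout > 0) return("dropout")
  if (!feasible) {
    return(if (identical(reason, "stutter")) "stutter_error" else "discordant")
  }
  "suitable"
}

#' Repeatability of first-allele frequencies between replicate runs
#'
#' Pearson correlation of the first-allele frequency across varieties
#' shared by two replicate sequencing runs, per marker.
#'
#' @param profiles1,profiles2 [allele_profiles()] tibbles from the two
#'   replicates.
#' @param min_shared Minimum shared varieties per marker (default 3);
#'   markers with fewer raise an error.
#' @return Tibble `marker`, `n_shared`, `correlation`.
#' @export
replicate_repeatability <- function(profiles1, profiles2, min_shared = 3) {
  f1 <- function(p) {
    p |>
      dplyr::filter(.data$rank == 1) |>
      dplyr::select("variety", "marker", "freq")
  }
  joined <- dplyr::inner_join(f1(profiles1), f1(profiles2),
                              by = c("variety", "marker"),
                              suffix = c("_1", "_2"))
  if (nrow(joined) == 0) abort_ssr("replicates share no (variety, marker) cells")
  out <- joined |>
    dplyr::group_by(.data$marker) |>
    dplyr::summarise(n_shared = dplyr::n(),
                     correlation = if (dplyr::n() >= min_shared)
                       cor(.data$freq_1, .data$freq_2) else NA_real_,
                     .groups = "drop")
  short <- out$marker[out$n_shared < min_shared]
  if (length(short) > 0) {
    abort_ssr(paste0("fewer than ", min_shared, " shared varieties for marker(s): ",
                     paste(short, collapse = ", ")))
  }
  out
}

#' Calibrate a marker panel against a CE reference database
#'
#' Full per-marker calibration: estimates the CE size offset (pairing the
#' top sequenced alleles according to the reference zygosity), the
#' feasible alpha interval and optimum, allele dropout, and the
#' suitability classification.
#'
#' @param profiles [allele_profiles()] tibble for the calibration
#'   varieties.
#' @param reference CE-scale genotype table.
#' @param panel Marker panel; markers absent from `profiles` or
#'   `reference` are skipped.
#' @param min_depth Per-variety depth below which a variety is excluded
#'   from calibration.
#' @param depth_threshold Average-depth cutoff for the `low_depth`
#'   classification.
#' @return An `ssr_calibration` object: a tibble with one row per marker
#'   (`marker`, `species`, `avg_depth`, `ce_offset`, `alpha_min`,
#'   `alpha_opt`, `alpha_max`, `feasible`, `reason`, `n_calibration`,
#'   `n_dropout`, `dropout_varieties` list column, `classification`),
#'   with the full dropout table in `attr(, "dropout")`.
#' @seealso [tidy.ssr_calibration()], [glance.ssr_calibration()],
#'   [autoplot.ssr_calibration()], [calibrated_panel()]
#' @export
calibrate_markers <- function(profiles, reference, panel, min_depth = 10,
                              depth_threshold = 50) {
  panel <- marker_panel(panel)
  markers <- intersect(panel$name, intersect(unique(profiles$marker),
                                             unique(reference$marker)))
  if (length(markers) == 0) abort_ssr("no markers shared by profiles, reference and panel")
  ref_varieties <- unique(reference$variety)
  avg <- average_depth(
    profiles |>
      dplyr::distinct(.data$variety, .data$marker, .data$total_depth) |>
      dplyr::transmute(.data$variety, .data$marker,
                       allele_length = 0L, count = .data$total_depth),
    varieties = ref_varieties
  )

  # Reference-guided pseudo-calls used only for offset estimation: the top
  # allele (reference homozygote) or top two alleles (reference
  # heterozygote), avoiding the circularity that calling with alpha would
  # itself need the offset.
  pseudo <- profiles |>
    dplyr::filter(.data$marker %in% markers,
                  .data$total_depth >= min_depth, .data$rank <= 2) |>
    dplyr::group_by(.data$variety, .data$marker) |>
    dplyr::summarise(
      top1 = .data$allele_length[.data$rank == 1],
      top2 = if (any(.data$rank == 2)) .data$allele_length[.data$rank == 2] else NA_integer_,
      .groups = "drop"
    ) |>
    dplyr::inner_join(dplyr::filter(reference, !is.na(.data$allele_a)),
                      by = c("variety", "marker")) |>
    dplyr::mutate(
      het = .data$allele_a != .data$allele_b,
      g_a = ifelse(.data$het & !is.na(.data$top2),
                   pmin(.data$top1, .data$top2), .data$top1),
      g_b = ifelse(.data$het & !is.na(.data$top2),
                   pmax(.data$top1, .data$top2), .data$top1)
    ) |>
    dplyr::transmute(.data$variety, .data$marker,
                     allele_a = .data$g_a, allele_b = .data$g_b)
  offsets <- estimate_size_offsets(pseudo, reference)
  dropout <- detect_allele_dropout(profiles, reference, offsets, min_depth)

  rows <- lapply(markers, function(m) {
    off <- offsets$ce_offset[offsets$marker == m]
    if (length(off) == 0) off <- NA_integer_
    ml <- panel$motif_length[panel$name == m]
    if (is.na(off)) {
      rng <- estimate_alpha_range(profiles, reference, offset = 0,
                                  min_depth = min_depth, motif_length = ml,
                                  marker = m)
      rng$feasible <- FALSE
      if (rng$reason == "ok") rng$reason <- "no_varieties"
    } else {
      rng <- estimate_alpha_range(profiles, reference, offset = off,
                                  min_depth = min_depth, motif_length = ml,
                                  marker = m)
    }
    drop_m <- dropout[dropout$marker == m, ]
    ad <- avg$avg_depth[avg$marker == m]
    if (length(ad) == 0) ad <- 0
    tibble::tibble(
      marker = m,
      species = panel$species[panel$name == m],
      avg_depth = ad,
      ce_offset = as.integer(off),
      alpha_min = rng$alpha_min, alpha_opt = rng$alpha_opt,
      alpha_max = rng$alpha_max,
      feasible = rng$feasible, reason = rng$reason,
      n_calibration = rng$n_calibration,
      n_dropout = nrow(drop_m),
      dropout_varieties = list(unique(drop_m$variety)),
      classification = classify_marker(ad, nrow(drop_m), rng$feasible,
                                       rng$reason, depth_threshold)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "dropout") <- dropout
  attr(out, "offset_report") <- attr(offsets, "report")
  class(out) <- c("ssr_calibration", class(out))
  out
}

#' Transfer calibration results into a marker panel
#'
#' Sets `alpha` (the optimum) and `ce_offset` for markers classified
#' `"suitable"`; other markers keep their previous values.
#'
#' @param panel Marker panel.
#' @param calibration `ssr_calibration` from [calibrate_markers()].
#' @param keep_unsuitable Keep unsuitable markers in the panel (default
#'   drops them, mirroring database construction).
#' @return The updated panel.
#' @export
calibrated_panel <- function(panel, calibration, keep_unsuitable = FALSE) {
  panel <- marker_panel(panel)
  good <- calibration[calibration$classification == "suitable", ]
  i <- match(panel$name, good$marker)
  panel$alpha <- ifelse(is.na(i), panel$alpha, good$alpha_opt[i])
  panel$ce_offset <- as.integer(ifelse(is.na(i), panel$ce_offset,
                                       good$ce_offset[i]))
  if (!keep_unsuitable) {
    panel <- panel[panel$name %in% good$marker | !panel$name %in% calibration$marker, ]
  }
  marker_panel(panel)
}

#' Write a calibration report
#'
#' Writes the per-marker calibration as both JSON (one object per marker)
#' and a human-readable TSV.
#'
#' @param calibration `ssr_calibration` object.
#' @param json_path,tsv_path Output paths (`NULL` skips either).
#' @return Invisibly, the list written to JSON.
#' @export
write_calibration_report <- function(calibration, json_path = NULL,
                                     tsv_path = NULL) {
  flat <- tidy(calibration)
  recs <- lapply(seq_len(nrow(calibration)), function(i) {
    r <- calibration[i, ]
    list(marker = r$marker, species = r$species,
         avg_depth = r$avg_depth, ce_offset = r$ce_offset,
         alpha_min = r$alpha_min, alpha_opt = r$alpha_opt,
         alpha_max = r$alpha_max, feasible = r$feasible,
         reason = r$reason, n_calibration = r$n_calibration,
         dropout_varieties = r$dropout_varieties[[1]],
         classification = r$classification)
  })
  names(recs) <- calibration$marker
  if (!is.null(json_path)) {
    jsonlite::write_json(recs, json_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  if (!is.null(tsv_path)) readr::write_tsv(flat, tsv_path, na = "")
  invisible(recs)
}
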