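# Synthetic paired-end amplicon data with known truth. The generator
# emulates the error modes that matter for length-based SSR genotyping:
# PCR stutter one motif unit below the template allele (strongest for
# dinucleotide repeats), +/-1 bp slippage, allele-specific amplification
# bias in heterozygotes, allele dropout from primer-site variation,
# substitution sequencing errors, and overdispersed (negative binomial)
# per-marker read depths.

#' Generate a synthetic SSR marker panel
#'
#' Random primers and flanking sequences are rejection-sampled so that no
#' primer (or its reverse complement) occurs internally in any amplicon,
#' and each marker receives a pool of alleles (repeat counts) with random
#' pool frequencies.
#'
#' @param n_markers Number of markers.
#' @param seed Integer seed; the panel is fully determined by it.
#' @param motif_lengths Candidate motif lengths (bp), recycled over
#'   markers.
#' @param n_alleles Alleles per marker pool (recycled).
#' @param repeat_range Range of repeat counts alleles are drawn from.
#' @param primer_length,flank_length Lengths (bp) of primers and of the
#'   constant flanks between primer and repeat tract.
#' @param species Species label stored in the panel.
#' @return A tibble with the marker-panel columns plus `flank_left`,
#'   `flank_right`, `alleles` (list of repeat counts) and `pool_freqs`
#'   (list of pool frequencies), classed `ssr_sim_panel`.
#' @export
sim_marker_panel <- function(n_markers = 6, seed = 1,
                             motif_lengths = c(3, 4, 5),
                             n_alleles = 4,
                             repeat_range = c(8, 16),
                             primer_length = 20, flank_length = 25,
                             species = "simulated") {
  withr::local_seed(seed)
  motif_lengths <- rep_len(motif_lengths, n_markers)
  n_alleles <- rep_len(n_alleles, n_markers)
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
  rows <- vector("list", n_markers)
  seen_primers <- character(0)
  for (m in seq_len(n_markers)) {
    ml <- motif_lengths[m]
    repeat {
      motif <- rand_seq(ml)
      # homopolymer motifs make the tract a slippage trap; skip them
      if (length(unique(strsplit(motif, "")[[1]])) > 1) break
    }
    reps <- sort(sample(seq(repeat_range[1], repeat_range[2]), n_alleles[m]))
    freqs <- rgamma(n_alleles[m], shape = 2)
    freqs <- freqs / sum(freqs)
    repeat {
      fwd <- rand_seq(primer_length)
      rev <- rand_seq(primer_length)
      fl <- rand_seq(flank_length)
      fr <- rand_seq(flank_length)
      tract <- strrep(motif, max(reps) + 2)
      insert <- paste0(fl, tract, fr)   # everything between the primers
      probes <- c(fwd, rev, revcomp(fwd), revcomp(rev))
      internal_hit <- any(vapply(probes, grepl, logical(1), x = insert,
                                 fixed = TRUE))
      if (!internal_hit && !fwd %in% seen_primers && !rev %in% seen_primers &&
          fwd != rev) break
    }
    seen_primers <- c(seen_primers, fwd, rev)
    rows[[m]] <- tibble::tibble(
      name = sprintf("SIM%02d", m), species = species,
      forward_primer = fwd, reverse_primer = rev,
      motif = motif, motif_length = as.integer(ml),
      alpha = NA_real_, ce_offset = NA_integer_,
      flank_left = fl, flank_right = fr,
      alleles = list(reps), pool_freqs = list(freqs)
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ssr_sim_panel", class(out))
  out
}

#' Build a simulation configuration
#'
#' Defaults describe a well-behaved amplicon experiment: overdispersed
#' depths around 200 reads per marker and variety, 1% stutter for motifs
#' of 3 bp and longer (10% for dinucleotides), 1% slippage, 0.1%
#' substitution errors, and up to 1.3-fold amplification bias between the
#' two alleles of a heterozygote.
#'
#' @param panel `ssr_sim_panel` from [sim_marker_panel()].
#' @param varieties Variety labels (default `V01`...).
#' @param n_varieties Used when `varieties` is `NULL`.
#' @param genotypes Optional fixed truth: tibble `variety`, `marker`,
#'   `repeats_a`, `repeats_b` (repeat counts from the marker's pool).
#'   When `NULL`, genotypes are Hardy-Weinberg draws from the pool
#'   frequencies.
#' @param mean_depth Mean reads per (marker, variety); scalar or named by
#'   marker.
#' @param dispersion Negative-binomial size parameter (larger = less
#'   overdispersed).
#' @param stutter_prob Probability that a read stutters one motif unit
#'   down; scalar or named by motif length (`"2"`..`"5"`).
#' @param slippage_prob Probability of a +/-1 bp slippage read (split
#'   evenly between +1 and -1).
#' @param seq_error_rate Per-base substitution probability.
#' @param amp_bias Maximum amplification ratio between heterozygote
#'   alleles; the per-cell ratio is drawn uniformly from
#'   `[1, amp_bias]` and assigned to a random allele.
#' @param dropout Tibble `marker`, `variety`, `repeats`: reads from that
#'   allele are suppressed entirely (amplification factor 0).
#' @param read_length Read length in bp.
#' @param seed Integer seed governing all randomness downstream.
#' @return A list classed `ssr_sim_config`.
#' @export
sim_config <- function(panel, varieties = NULL, n_varieties = 20,
                       genotypes = NULL, mean_depth = 200, dispersion = 5,
                       stutter_prob = c("2" = 0.10, "3" = 0.01,
                                        "4" = 0.01, "5" = 0.01),
                       slippage_prob = 0.01, seq_error_rate = 0.001,
                       amp_bias = 1.3,
                       dropout = NULL, read_length = 150, seed = 1) {
  if (is.null(varieties)) varieties <- sprintf("V%02d", seq_len(n_varieties))
  if (anyDuplicated(varieties)) abort_ssr("variety labels must be unique")
  stopifnot(all(unlist(stutter_prob) >= 0, unlist(stutter_prob) <= 1),
            slippage_prob >= 0, slippage_prob <= 1,
            seq_error_rate >= 0, seq_error_rate <= 1, amp_bias >= 1)
  if (read_length < max(nchar(panel$forward_primer),
                        nchar(panel$reverse_primer)) + 1) {
    abort_ssr("read_length must exceed the primer length")
  }
  if (length(stutter_prob) == 1 && is.null(names(stutter_prob))) {
    stutter_prob <- setNames(rep(stutter_prob, 4), as.character(2:5))
  }
  cfg <- list(panel = panel, varieties = varieties, genotypes = genotypes,
              mean_depth = mean_depth, dispersion = dispersion,
              stutter_prob = stutter_prob, slippage_prob = slippage_prob,
              seq_error_rate = seq_error_rate, amp_bias = amp_bias,
              dropout = dropout %||%
                tibble::tibble(marker = character(), variety = character(),
                               repeats = integer()),
              read_length = as.integer(read_length), seed = as.integer(seed))
  # every pool allele must produce a mergeable amplicon: the two reads
  # must overlap by at least 10 bp
  for (m in seq_len(nrow(panel))) {
    lens <- sim_amplicon_length(panel[m, ], unlist(panel$alleles[m]))
    too_long <- lens > 2L * cfg$read_length - 10L
    if (any(too_long)) {
      abort_ssr(paste0("amplicons of marker ", panel$name[m],
                       " are too long to merge at read_length ",
                       cfg$read_length))
    }
  }
  class(cfg) <- "ssr_sim_config"
  cfg
}

sim_amplicon_length <- function(panel_row, repeats) {
  nchar(panel_row$forward_primer) + nchar(panel_row$flank_left) +
    repeats * panel_row$motif_length +
    nchar(panel_row$flank_right) + nchar(panel_row$reverse_primer)
}

sim_amplicon <- function(panel_row, repeats, slip = 0L) {
  tract <- strrep(panel_row$motif, repeats)
  if (slip == 1L) {
    tract <- paste0(tract, substr(panel_row$motif, panel_row$motif_length,
                                  panel_row$motif_length))
  } else if (slip == -1L) {
    tract <- substr(tract, 1L, nchar(tract) - 1L)
  }
  paste0(panel_row$forward_primer, panel_row$flank_left, tract,
         panel_row$flank_right, revcomp(panel_row$reverse_primer))
}

#' Draw true genotypes
#'
#' Fixed genotypes in the configuration pass through unchanged; otherwise
#' each (variety, marker) receives two independent draws from the
#' marker's allele-pool frequencies (Hardy-Weinberg sampling).
#' Deterministic given the configuration seed.
#'
#' @param config `ssr_sim_config`.
#' @return Truth tibble `variety`, `marker`, `repeats_a`, `repeats_b`,
#'   `len_a`, `len_b` (digital amplicon lengths, `repeats_a <= repeats_b`).
#' @export
simulate_truth <- function(config) {
  panel <- config$panel
  withr::local_seed(config$seed)
  if (!is.null(config$genotypes)) {
    g <- tibble::as_tibble(config$genotypes)
  } else {
    grid <- tidyr::expand_grid(variety = config$varieties, marker = panel$name)
    draws <- purrr::map2(grid$variety, grid$marker, function(v, m) {
      row <- panel[panel$name == m, ]
      pool <- unlist(row$alleles)
      if (length(pool) == 0) abort_ssr(paste0("empty allele pool for ", m))
      sort(sample(pool, 2, replace = TRUE, prob = unlist(row$pool_freqs)))
    })
    g <- grid
    g$repeats_a <- vapply(draws, `[`, integer(1), 1)
    g$repeats_b <- vapply(draws, `[`, integer(1), 2)
  }
  i <- match(g$marker, panel$name)
  bad <- mapply(function(ra, rb, k) !(ra %in% panel$alleles[[k]] &&
                                        rb %in% panel$alleles[[k]]),
                g$repeats_a, g$repeats_b, i)
  if (any(bad)) abort_ssr("fixed genotypes contain alleles outside the marker pool")
  g$len_a <- sim_amplicon_length(panel[i, ], pmin(g$repeats_a, g$repeats_b))
  g$len_b <- sim_amplicon_length(panel[i, ], pmax(g$repeats_a, g$repeats_b))
  g
}

#' Simulate paired reads from a truth table
#'
#' For every (variety, marker): a negative-binomial read depth; per read a
#' source allele drawn with amplification bias and dropout factors;
#' stutter, slippage and substitution errors applied; the amplicon split
#' into a forward prefix read and reverse-complemented suffix read of
#' `read_length` (capped at the amplicon length), with constant Phred 35
#' qualities.
#'
#' @param truth Tibble from [simulate_truth()].
#' @param config `ssr_sim_config`.
#' @return List classed `ssr_simulation`: `reads` (tibble `variety`,
#'   `id`, `r1`, `r2`), `truth` (the input truth augmented with realized
#'   per-allele and artifact read counts) and `config`.
#' @export
simulate_reads <- function(truth, config) {
  panel <- config$panel
  withr::local_seed((config$seed + 1L) %% 2147483647L)
  mean_depth <- config$mean_depth
  if (is.null(names(mean_depth))) {
    mean_depth <- setNames(rep_len(mean_depth, nrow(panel)), panel$name)
  }
  all_reads <- vector("list", nrow(truth))
  truth$depth <- 0L
  truth$n_from_a <- 0L
  truth$n_from_b <- 0L
  truth$n_stutter <- 0L
  truth$n_slippage <- 0L
  truth$n_error <- 0L
  for (r in seq_len(nrow(truth))) {
    v <- truth$variety[r]
    m <- truth$marker[r]
    row <- panel[panel$name == m, ]
    n <- rnbinom(1, size = config$dispersion, mu = mean_depth[[m]])
    if (n == 0) next
    reps <- c(truth$repeats_a[r], truth$repeats_b[r])
    w <- c(1, 1)
    if (reps[1] != reps[2] && config$amp_bias > 1) {
      ratio <- runif(1, 1, config$amp_bias)
      if (runif(1) < 0.5) w <- c(ratio, 1) else w <- c(1, ratio)
    }
    drop <- config$dropout
    w[1] <- w[1] * !any(drop$marker == m & drop$variety == v &
                          drop$repeats == reps[1])
    w[2] <- w[2] * !any(drop$marker == m & drop$variety == v &
                          drop$repeats == reps[2])
    if (reps[1] == reps[2]) w <- c(max(w), 0)
    if (sum(w) == 0) next
    src <- sample(1:2, n, replace = TRUE, prob = w / sum(w))
    read_reps <- reps[src]
    p_st <- unname(config$stutter_prob[as.character(row$motif_length)])
    if (is.na(p_st)) p_st <- 0
    stutter <- runif(n) < p_st & read_reps >= 2L
    read_reps <- read_reps - stutter
    slip <- integer(n)
    do_slip <- runif(n) < config$slippage_prob
    slip[do_slip] <- sample(c(-1L, 1L), sum(do_slip), replace = TRUE)
    # build each distinct (repeats, slip) template once
    key <- paste(read_reps, slip)
    ukey <- unique(key)
    templates <- vapply(ukey, function(k) {
      parts <- as.integer(strsplit(k, " ")[[1]])
      sim_amplicon(row, parts[1], parts[2])
    }, character(1))
    amp <- unname(templates[match(key, ukey)])
    # substitution errors
    n_err <- rbinom(n, nchar(amp), config$seq_error_rate)
    has_err <- which(n_err > 0)
    for (i in has_err) {
      chars <- strsplit(amp[i], "")[[1]]
      pos <- sample(length(chars), min(n_err[i], length(chars)))
      chars[pos] <- vapply(chars[pos], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      amp[i] <- paste(chars, collapse = "")
    }
    L <- nchar(amp)
    rl <- pmin(config$read_length, L)
    r1 <- substr(amp, 1L, rl)
    r2 <- revcomp(substr(amp, L - rl + 1L, L))
    all_reads[[r]] <- tibble::tibble(
      variety = v,
      id = sprintf("%s:%s:%d", v, m, seq_len(n)),
      r1 = r1, r2 = r2
    )
    truth$depth[r] <- n
    truth$n_from_a[r] <- sum(src == 1L)
    truth$n_from_b[r] <- sum(src == 2L)
    truth$n_stutter[r] <- sum(stutter)
    truth$n_slippage[r] <- sum(do_slip)
    truth$n_error[r] <- length(has_err)
  }
  out <- list(reads = dplyr::bind_rows(all_reads), truth = truth,
              config = config)
  class(out) <- "ssr_simulation"
  out
}

#' Simulate a complete dataset
#'
#' @param config `ssr_sim_config`.
#' @return `ssr_simulation` (see [simulate_reads()]).
#' @export
simulate_dataset <- function(config) {
  simulate_reads(simulate_truth(config), config)
}

#' Write a simulation to disk
#'
#' One pair of FASTQ files per variety (`<variety>_R1.fastq[.gz]`,
#' `_R2`), the marker panel as TSV, and the truth table as TSV.
#'
#' @param sim `ssr_simulation` object.
#' @param dir Output directory (created if needed).
#' @param gzip Compress the FASTQ files.
#' @return `dir`, invisibly.
#' @export
sim_write <- function(sim, dir, gzip = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  qual35 <- function(seqs) lapply(nchar(seqs), function(n) rep(35L, n))
  for (v in sim$config$varieties) {
    reads <- sim$reads[sim$reads$variety == v, ]
    write_fastq(tibble::tibble(id = reads$id, seq = reads$r1,
                               qual = qual35(reads$r1)),
                file.path(dir, paste0(v, "_R1", ext)))
    write_fastq(tibble::tibble(id = reads$id, seq = reads$r2,
                               qual = qual35(reads$r2)),
                file.path(dir, paste0(v, "_R2", ext)))
  }
  write_marker_panel(marker_panel(sim$config$panel[, c(
    "name", "species", "forward_primer", "reverse_primer", "motif",
    "motif_length", "alpha", "ce_offset")]),
    file.path(dir, "panel.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Truth table as a genotype table
#'
#' @param truth Tibble from [simulate_truth()].
#' @param scale `"gbs"` for digital lengths.
#' @return Long-format genotype table of the true genotypes.
#' @export
truth_genotypes <- function(truth, scale = "gbs") {
  genotype_table(tibble::tibble(
    variety = truth$variety, marker = truth$marker,
    allele_a = truth$len_a, allele_b = truth$len_b
  ))
}

#' Compare calls against simulated truth
#'
#' @param calls [call_genotypes()] output (GBS scale).
#' @param truth Tibble from [simulate_truth()] (or a simulation's
#'   `$truth`).
#' @return List with `accuracy` (exact-genotype accuracy over called
#'   cells), `n_called`, `n_cells`, `status_counts` (tibble) and
#'   `errors` (tibble of miscalled cells).
#' @export
evaluate_calls <- function(calls, truth) {
  truth_gt <- truth_genotypes(truth)
  if (length(intersect(unique(calls$variety), unique(truth_gt$variety))) == 0) {
    abort_ssr("calls and truth share no varieties")
  }
  joined <- dplyr::inner_join(
    tibble::as_tibble(calls), truth_gt,
    by = c("variety", "marker"), suffix = c("_call", "_true")
  )
  called <- dplyr::filter(joined, .data$status == "called")
  correct <- called$allele_a_call == called$allele_a_true &
    called$allele_b_call == called$allele_b_true
  list(
    accuracy = if (nrow(called) > 0) mean(correct) else NA_real_,
    n_called = nrow(called),
    n_cells = nrow(joined),
    status_counts = dplyr::count(joined, .data$status),
    errors = called[!correct, c("variety", "marker", "allele_a_call",
                                "allele_b_call", "allele_a_true",
                                "allele_b_true")]
  )
}
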