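# Shared fixtures and independent oracles, all built in code.

# --- tiny hand-built panel -------------------------------------------------

tiny_panel <- function() {
  marker_panel(tibble::tibble(
    name = c("MK1", "MK2"),
    species = "test",
    forward_primer = c("ACGTACGTCC", "TTGGCCAAGG"),
    reverse_primer = c("GGTTCCAAGG", "AACCGGTTAA"),
    motif = c("AAT", "ACAG"),
    motif_length = c(3L, 4L),
    alpha = c(0.75, 0.75),
    ce_offset = c(0L, 0L)
  ))
}

# amplicon for a tiny_panel marker with a given repeat count
tiny_amplicon <- function(panel, marker, repeats,
                          flank_l = "GATTACAGAT", flank_r = "CTTAGGCTTA") {
  row <- panel[panel$name == marker, ]
  paste0(row$forward_primer, flank_l, strrep(row$motif, repeats), flank_r,
         revcomp(row$reverse_primer))
}

# --- profile builders ------------------------------------------------------

# build an allele-profile tibble directly from named count vectors:
# profiles_from_counts(V1 = c(`181` = 90, `185` = 10), ...)
profiles_from_counts <- function(..., marker = "MK1") {
  cells <- list(...)
  counts <- purrr::imap(cells, function(cnt, v) {
    tibble::tibble(variety = v, marker = marker,
                   allele_length = as.integer(names(cnt)),
                   count = as.integer(cnt))
  })
  allele_profiles(dplyr::bind_rows(counts))
}

# reference genotype table from variety -> c(a, b)
reference_from_pairs <- function(pairs, marker = "MK1") {
  genotype_table(tibble::tibble(
    variety = names(pairs),
    marker = marker,
    allele_a = vapply(pairs, `[`, numeric(1), 1),
    allele_b = vapply(pairs, `[`, numeric(1), 2)
  ))
}

# --- independent oracles ---------------------------------------------------

# Grid-search oracle for the feasible alpha interval: try every alpha on a
# 0.01 grid, call every variety with a self-contained implementation of the
# threshold rule, and keep the alphas with perfect concordance.
oracle_alpha_grid <- function(profiles, reference, offset, min_depth = 10,
                              step = 0.01) {
  marker <- unique(profiles$marker)
  ref <- reference[reference$marker == marker & !is.na(reference$allele_a), ]
  prof <- profiles[profiles$marker == marker &
                     profiles$total_depth >= min_depth, ]
  varieties <- intersect(unique(prof$variety), ref$variety)
  grid <- seq(0, 1, by = step)
  keep <- logical(length(grid))
  if (length(varieties) == 0) return(numeric(0))
  for (g in seq_along(grid)) {
    a <- grid[g]
    if (a == 0) next                       # alpha must be in (0, 1]
    ok <- TRUE
    for (v in varieties) {
      p <- prof[prof$variety == v, ]
      p <- p[order(p$rank), ]
      called <- if (p$freq[1] > a) {
        rep(p$allele_length[1], 2)
      } else if (nrow(p) >= 2) {
        sort(p$allele_length[1:2])
      } else {
        NULL
      }
      r <- ref[ref$variety == v, ]
      expect_pair <- sort(c(r$allele_a, r$allele_b))
      if (is.null(called) || !all(called + offset == expect_pair)) {
        ok <- FALSE
        break
      }
    }
    keep[g] <- ok
  }
  grid[keep]
}

# Brute-force marker assignment: scan every (marker, orientation) and test
# anchored primer equality (exact matching only).
oracle_assign <- function(read, panel) {
  hits <- character(0)
  for (m in seq_len(nrow(panel))) {
    f <- panel$forward_primer[m]
    rrc <- revcomp(panel$reverse_primer[m])
    for (seqv in c(read, revcomp(read))) {
      if (nchar(seqv) < nchar(f) + nchar(rrc)) next
      if (startsWith(seqv, f) && endsWith(seqv, rrc)) {
        hits <- c(hits, panel$name[m])
        break
      }
    }
  }
  hits <- unique(hits)
  if (length(hits) == 0) return(NA_character_)
  if (length(hits) > 1) return("ambiguous")
  hits
}

# Random calibration fixture with known feasibility structure. Frequencies
# are exact multiples of 1/1000 so interval endpoints are exactly
# representable.
random_calibration_fixture <- function(seed, n_varieties = 8,
                                       allow_mismatch = FALSE) {
  withr::local_seed(seed)
  motif <- 4L
  pool <- seq(150L, 170L, by = motif)
  offset <- sample(-4:3, 1)
  varieties <- sprintf("V%02d", seq_len(n_varieties))
  counts <- list()
  ref <- list()
  for (v in varieties) {
    het <- runif(1) < 0.5
    mismatch <- allow_mismatch && runif(1) < 0.15
    if (het) {
      alleles <- sort(sample(pool, 2))
      c1 <- sample(350:650, 1)            # one real allele in [0.35, 0.65]
      c3 <- sample(1:20, 1)               # trace artifact, never ranks top-2
      c2 <- 1000L - c1 - c3
      top2 <- if (mismatch) alleles[2] + motif else alleles[2]
      cnt <- c(c1, c2, c3)
      names(cnt) <- c(alleles[1], top2, alleles[1] - motif)
    } else {
      alleles <- rep(sample(pool, 1), 2)
      c1 <- sample(700:980, 1)            # f1 in [0.70, 0.98]
      c3 <- sample(1:10, 1)
      c2 <- 1000L - c1 - c3
      top1 <- if (mismatch) alleles[1] + motif else alleles[1]
      cnt <- c(c1, c2, c3)
      names(cnt) <- c(top1, alleles[1] - motif, alleles[1] + 2L * motif)
    }
    cnt <- cnt[cnt > 0]
    counts[[v]] <- cnt
    ref[[v]] <- alleles + offset
  }
  profiles <- do.call(profiles_from_counts, counts)
  list(profiles = profiles,
       reference = reference_from_pairs(ref),
       offset = offset)
}

# in-memory FASTQ writer for constructed read sets
write_test_fastq <- function(ids, seqs, path, qual = 35L) {
  lines <- unlist(mapply(function(id, s) {
    c(paste0("@", id), s, "+", strrep(intToUtf8(qual + 33L), nchar(s)))
  }, ids, seqs, SIMPLIFY = FALSE))
  if (length(lines) == 0) lines <- character(0)
  writeLines(as.character(lines), path)
  path
}
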