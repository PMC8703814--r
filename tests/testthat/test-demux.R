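test_that("reads are assigned by anchored primer matching in both orientations", {
  panel <- tiny_panel()
  amp <- tiny_amplicon(panel, "MK1", 5)
  res <- assign_markers(c(amp, revcomp(amp), "ACGTACGTACGTACGTACGTACGTACGTACGT"),
                        panel)
  expect_equal(res$assignment, c("assigned", "assigned", "unassigned"))
  expect_equal(res$marker[1:2], c("MK1", "MK1"))
})

test_that("reads matching two markers are ambiguous, not assigned", {
  p <- marker_panel(tibble::tibble(
    name = c("A", "B"), species = "t",
    forward_primer = "ACGTACGTCC",
    # B's reverse primer is a suffix-compatible truncation of A's
    reverse_primer = c("GGTTCCAAGGTTCCA", "GGTTCCAAGG"),
    motif = "AAT", motif_length = 3L
  ))
  read <- paste0("ACGTACGTCC", "AATAATAAT", revcomp("GGTTCCAAGGTTCCA"))
  res <- assign_markers(read, p)
  expect_equal(res$assignment, "ambiguous")
  expect_true(is.na(res$marker))
})

test_that("assignment matches a brute-force oracle on random panels", {
  withr::local_seed(21)
  bases <- c("A", "C", "G", "T")
  rs <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
  for (trial in 1:5) {
    n_mark <- sample(3:10, 1)
    panel <- marker_panel(tibble::tibble(
      name = sprintf("M%02d", seq_len(n_mark)), species = "t",
      forward_primer = replicate(n_mark, rs(12)),
      reverse_primer = replicate(n_mark, rs(12)),
      motif = "AAT", motif_length = 3L
    ))
    reads <- c(
      vapply(sample(n_mark, 6, replace = TRUE), function(m)
        paste0(panel$forward_primer[m], rs(20), strrep("AAT", 5),
               revcomp(panel$reverse_primer[m])), character(1)),
      replicate(4, rs(50))
    )
    flip <- sample(length(reads), 3)
    reads[flip] <- revcomp(reads[flip])
    got <- assign_markers(reads, panel)
    want <- vapply(reads, oracle_assign, character(1), panel = panel)
    expect_equal(ifelse(got$assignment == "assigned", got$marker,
                        ifelse(got$assignment == "ambiguous", "ambiguous",
                               NA_character_)),
                 unname(want))
  }
})

test_that("assignment partitions reads and tolerates primer mismatches only when asked", {
  panel <- tiny_panel()
  amp <- tiny_amplicon(panel, "MK2", 6)
  mutated <- amp
  substr(mutated, 3, 3) <- if (substr(mutated, 3, 3) == "G") "C" else "G"
  res0 <- assign_markers(c(amp, mutated), panel, max_mismatches = 0)
  expect_equal(res0$assignment, c("assigned", "unassigned"))
  res1 <- assign_markers(c(amp, mutated), panel, max_mismatches = 1)
  expect_equal(res1$assignment, c("assigned", "assigned"))
  counts <- table(factor(res0$assignment,
                         c("assigned", "unassigned", "ambiguous")))
  expect_equal(sum(counts), 2)
})

test_that("IUPAC codes in primers match their base sets", {
  panel <- marker_panel(tibble::tibble(
    name = "M", species = "t",
    forward_primer = "ACGTACGTNR",    # N any, R = A/G
    reverse_primer = "GGTTCCAAGG",
    motif = "AAT", motif_length = 3L
  ))
  good <- paste0("ACGTACGTTA", strrep("AAT", 4), revcomp("GGTTCCAAGG"))
  bad <- paste0("ACGTACGTTC", strrep("AAT", 4), revcomp("GGTTCCAAGG"))
  expect_equal(assign_markers(c(good, bad), panel)$assignment,
               c("assigned", "unassigned"))
})

test_that("allele counting accumulates digital lengths per marker", {
  reads <- tibble::tibble(
    marker = "MK1",
    length = c(rep(181L, 90), rep(185L, 10)),
    assignment = "assigned"
  )
  counts <- count_alleles(reads, "Akane", markers = c("MK1", "MK2"))
  expect_equal(counts$count[counts$allele_length == 181], 90L)
  expect_equal(counts$count[counts$allele_length == 185], 10L)
  expect_equal(sum(counts$count), 100L)
  expect_equal(attr(counts, "zero_depth_markers"), "MK2")

  empty <- count_alleles(reads[0, ], "Akane", markers = "MK1")
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "zero_depth_markers"), "MK1")
})

test_that("the simulator's read counts are recovered exactly without noise", {
  panel <- sim_marker_panel(n_markers = 2, seed = 31)
  cfg <- sim_config(panel, n_varieties = 3, mean_depth = 60, seed = 31,
                    stutter_prob = 0, slippage_prob = 0, seq_error_rate = 0,
                    amp_bias = 1)
  sim <- simulate_dataset(cfg)
  plain <- marker_panel(sim$config$panel[, 1:8])
  for (v in cfg$varieties) {
    reads <- sim$reads[sim$reads$variety == v, ]
    merged <- mapply(function(a, b) {
      merge_read_pair(list(id = "x", seq = a, qual = rep(35L, nchar(a))),
                      list(id = "x", seq = b, qual = rep(35L, nchar(b))))$seq
    }, reads$r1, reads$r2)
    asn <- assign_markers(unname(merged), plain)
    counts <- count_alleles(asn, v)
    truth_v <- sim$truth[sim$truth$variety == v, ]
    for (r in seq_len(nrow(truth_v))) {
      cm <- counts[counts$marker == truth_v$marker[r], ]
      expected <- table(c(rep(truth_v$len_a[r], truth_v$n_from_a[r]),
                          rep(truth_v$len_b[r], truth_v$n_from_b[r])))
      expect_equal(setNames(cm$count, cm$allele_length),
                   setNames(as.integer(expected), names(expected)))
    }
  }
})

test_that("allele profiles report top-k frequencies over total depth", {
  prof <- profiles_from_counts(
    V1 = c(`181` = 90, `185` = 5, `178` = 3, `190` = 2)
  )
  expect_equal(prof$freq, c(0.90, 0.05, 0.03, 0.02))
  expect_equal(prof$allele_length[1], 181L)

  # five lengths: top-4 frequencies sum to 0.98 < 1
  prof5 <- profiles_from_counts(
    V1 = c(`181` = 40, `185` = 40, `178` = 15, `190` = 3, `200` = 2)
  )
  expect_equal(sum(prof5$freq), 0.98)
  expect_equal(nrow(prof5), 4)

  # count ties break toward the smaller length
  tie <- profiles_from_counts(V1 = c(`185` = 50, `181` = 50))
  expect_equal(tie$allele_length[tie$rank == 1], 181L)

  # frequencies are non-increasing; with <= 4 lengths they sum to 1
  expect_true(all(diff(prof$freq) <= 0))
  expect_equal(sum(prof$freq), 1)
})

test_that("average depth is the arithmetic mean over varieties", {
  counts <- dplyr::bind_rows(
    tibble::tibble(variety = "A", marker = "M", allele_length = 100L, count = 10L),
    tibble::tibble(variety = "B", marker = "M", allele_length = 100L, count = 20L)
  )
  expect_equal(average_depth(counts)$avg_depth, 15)
  expect_equal(average_depth(counts[1, ])$avg_depth, 10)
  # a variety with zero reads for the marker drags the mean down
  expect_equal(average_depth(counts, varieties = c("A", "B", "C"))$avg_depth,
               10)
  expect_error(average_depth(counts[0, ]), "at least one variety")
})
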