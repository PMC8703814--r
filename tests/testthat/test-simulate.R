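test_that("simulation is fully deterministic given the seed", {
  panel <- sim_marker_panel(n_markers = 2, seed = 71)
  cfg <- sim_config(panel, n_varieties = 3, mean_depth = 40, seed = 71)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  expect_identical(sim_marker_panel(n_markers = 2, seed = 71), panel)
})

test_that("fixed genotypes pass through and pool membership is enforced", {
  panel <- sim_marker_panel(n_markers = 1, seed = 72)
  pool <- panel$alleles[[1]]
  fixed <- tibble::tibble(variety = c("A", "B"), marker = panel$name,
                          repeats_a = pool[1], repeats_b = pool[2])
  cfg <- sim_config(panel, varieties = c("A", "B"), genotypes = fixed,
                    seed = 72)
  tr <- simulate_truth(cfg)
  expect_equal(tr$repeats_a, fixed$repeats_a)
  expect_equal(tr$repeats_b, fixed$repeats_b)

  bad <- dplyr::mutate(fixed, repeats_b = max(pool) + 1L)
  cfg_bad <- sim_config(panel, varieties = c("A", "B"), genotypes = bad,
                        seed = 72)
  expect_error(simulate_truth(cfg_bad), "outside the marker pool")
})

test_that("Hardy-Weinberg draws give the expected heterozygote fraction", {
  panel <- sim_marker_panel(n_markers = 1, seed = 73, n_alleles = 2)
  panel$pool_freqs[[1]] <- c(0.5, 0.5)
  cfg <- sim_config(panel, n_varieties = 5000, seed = 73)
  tr <- simulate_truth(cfg)
  het <- mean(tr$repeats_a != tr$repeats_b)
  # expectation 0.5, binomial sd ~ 0.007
  expect_lt(abs(het - 0.5), 0.03)
})

test_that("read counts are conserved between truth and emitted reads", {
  panel <- sim_marker_panel(n_markers = 3, seed = 74)
  cfg <- sim_config(panel, n_varieties = 4, mean_depth = 50, seed = 74)
  sim <- simulate_dataset(cfg)
  per_cell <- table(sub(":[0-9]+$", "", sim$reads$id))
  for (r in seq_len(nrow(sim$truth))) {
    key <- paste0(sim$truth$variety[r], ":", sim$truth$marker[r])
    n <- if (key %in% names(per_cell)) as.integer(per_cell[[key]]) else 0L
    expect_equal(n, sim$truth$depth[r])
    expect_equal(sim$truth$n_from_a[r] + sim$truth$n_from_b[r],
                 sim$truth$depth[r])
  }
})

test_that("stutter produces reads one motif unit short at the configured rate", {
  panel <- sim_marker_panel(n_markers = 1, seed = 75, motif_lengths = 2)
  pool <- panel$alleles[[1]]
  fixed <- tibble::tibble(variety = "A", marker = panel$name,
                          repeats_a = max(pool), repeats_b = max(pool))
  cfg <- sim_config(panel, varieties = "A", genotypes = fixed,
                    mean_depth = 10000, dispersion = 1e6,
                    stutter_prob = c("2" = 0.2), slippage_prob = 0,
                    seq_error_rate = 0, seed = 75)
  sim <- simulate_dataset(cfg)
  true_len <- sim$truth$len_a[1]
  # merge each distinct pair once (noise-free data collapse to ~2 templates)
  key <- paste(sim$reads$r1, sim$reads$r2)
  uk <- unique(key)
  ulen <- vapply(uk, function(k) {
    p <- strsplit(k, " ")[[1]]
    merge_read_pair(list(id = "x", seq = p[1], qual = rep(35L, nchar(p[1]))),
                    list(id = "x", seq = p[2], qual = rep(35L, nchar(p[2]))))$length
  }, integer(1))
  lens <- unname(ulen[match(key, uk)])
  frac_stutter <- mean(lens == true_len - 2L)
  n <- length(lens)
  expect_lt(abs(frac_stutter - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  expect_equal(sim$truth$n_stutter[1], sum(lens == true_len - 2L))
})

test_that("noise-free homozygous cells yield identical read lengths", {
  panel <- sim_marker_panel(n_markers = 1, seed = 76)
  pool <- panel$alleles[[1]]
  fixed <- tibble::tibble(variety = "A", marker = panel$name,
                          repeats_a = pool[1], repeats_b = pool[1])
  cfg <- sim_config(panel, varieties = "A", genotypes = fixed,
                    mean_depth = 100, stutter_prob = 0, slippage_prob = 0,
                    seq_error_rate = 0, seed = 76)
  sim <- simulate_dataset(cfg)
  expect_equal(length(unique(sim$reads$r1)), 1L)
  expect_equal(length(unique(sim$reads$r2)), 1L)
})

test_that("a dropout factor of zero suppresses every read from that allele", {
  panel <- sim_marker_panel(n_markers = 1, seed = 77)
  pool <- panel$alleles[[1]]
  fixed <- tibble::tibble(variety = "A", marker = panel$name,
                          repeats_a = pool[1], repeats_b = pool[2])
  cfg <- sim_config(panel, varieties = "A", genotypes = fixed,
                    mean_depth = 300,
                    dropout = tibble::tibble(marker = panel$name,
                                             variety = "A",
                                             repeats = pool[2]),
                    seed = 77)
  sim <- simulate_dataset(cfg)
  expect_equal(sim$truth$n_from_b[1], 0L)
  expect_gt(sim$truth$n_from_a[1], 0L)
})

test_that("unmergeable amplicon configurations are rejected", {
  panel <- sim_marker_panel(n_markers = 1, seed = 78)
  expect_error(sim_config(panel, read_length = 60), "too long to merge")
})

test_that("written FASTQ files reproduce the in-memory reads", {
  panel <- sim_marker_panel(n_markers = 2, seed = 79)
  cfg <- sim_config(panel, n_varieties = 2, mean_depth = 30, seed = 79)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  sim_write(sim, dir)
  expect_true(file.exists(file.path(dir, "panel.tsv")))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  v <- cfg$varieties[1]
  back <- Biostrings::readDNAStringSet(file.path(dir, paste0(v, "_R1.fastq.gz")),
                                       format = "fastq")
  expect_equal(unname(as.character(back)),
               sim$reads$r1[sim$reads$variety == v])
})

test_that("evaluate_calls scores exact genotype recovery", {
  panel <- sim_marker_panel(n_markers = 2, seed = 80)
  cfg <- sim_config(panel, n_varieties = 3, mean_depth = 100, seed = 80)
  tr <- simulate_truth(cfg)
  perfect <- truth_genotypes(tr) |>
    dplyr::mutate(status = "called", total_depth = 100L,
                  first_allele_freq = 0.5)
  ev <- evaluate_calls(perfect, tr)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$n_called, nrow(tr))

  one_wrong <- perfect
  one_wrong$allele_a[1] <- one_wrong$allele_a[1] + 3L
  ev2 <- evaluate_calls(one_wrong, tr)
  expect_equal(ev2$accuracy, 1 - 1 / nrow(tr))

  stranger <- dplyr::mutate(perfect, variety = paste0("X", variety))
  expect_error(evaluate_calls(stranger, tr), "share no varieties")
})
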