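test_that("the alpha interval spans max het f1 to min hom f1", {
  profiles <- profiles_from_counts(
    H1 = c(`100` = 50, `104` = 50),            # het, f1 = 0.50
    H2 = c(`100` = 53, `104` = 47),            # het, f1 = 0.53
    O1 = c(`100` = 90, `96` = 10),             # hom, f1 = 0.90
    O2 = c(`100` = 95, `96` = 5)               # hom, f1 = 0.95
  )
  reference <- reference_from_pairs(list(
    H1 = c(100, 104), H2 = c(100, 104), O1 = c(100, 100), O2 = c(100, 100)
  ))
  rng <- estimate_alpha_range(profiles, reference, offset = 0)
  expect_true(rng$feasible)
  expect_equal(rng$alpha_min, 0.53)
  expect_equal(rng$alpha_max, 0.90)
  expect_equal(rng$alpha_opt, 0.72)
})

test_that("the optimum is the half-up midpoint at two decimals", {
  expect_equal(alpha_midpoint(0.45, 0.69), 0.57)
  expect_equal(alpha_midpoint(0.53, 0.96), 0.75)  # 0.745 rounds up
  expect_equal(alpha_midpoint(0.57, 0.90), 0.74)  # 0.735 rounds up
  expect_equal(alpha_midpoint(0.60, 0.61), 0.61)  # 0.605 rounds up
})

test_that("an allele-identity conflict makes the marker infeasible", {
  profiles <- profiles_from_counts(
    H1 = c(`100` = 55, `108` = 43, `96` = 2),   # second allele wrong
    O1 = c(`100` = 95, `96` = 5)
  )
  reference <- reference_from_pairs(list(H1 = c(100, 104), O1 = c(100, 100)))
  rng <- estimate_alpha_range(profiles, reference, offset = 0)
  expect_false(rng$feasible)
  expect_equal(rng$reason, "allele_mismatch")
  expect_equal(rng$mismatches[[1]]$variety, "H1")
  # grid oracle agrees: no alpha achieves concordance
  expect_length(oracle_alpha_grid(profiles, reference, 0), 0)
})

test_that("infeasibility from one-motif-unit artifacts is labelled stutter", {
  profiles <- profiles_from_counts(
    H1 = c(`100` = 60, `96` = 35, `104` = 5),   # top2 is the -1-motif band
    O1 = c(`100` = 95, `96` = 5)
  )
  reference <- reference_from_pairs(list(H1 = c(100, 104), O1 = c(100, 100)))
  rng <- estimate_alpha_range(profiles, reference, offset = 0,
                              motif_length = 4)
  expect_equal(rng$reason, "stutter")
  expect_equal(classify_marker(1000, 0, FALSE, rng$reason), "stutter_error")
  expect_equal(classify_marker(1000, 0, FALSE, "allele_mismatch"),
               "discordant")
})

test_that("estimated intervals agree with the grid-search oracle", {
  for (seed in 1:30) {
    fx <- random_calibration_fixture(seed, allow_mismatch = seed %% 3 == 0)
    rng <- estimate_alpha_range(fx$profiles, fx$reference, fx$offset)
    grid <- oracle_alpha_grid(fx$profiles, fx$reference, fx$offset)
    if (!rng$feasible) {
      expect_length(grid, 0)
    } else {
      expect_gt(length(grid), 0)
      expect_lt(abs(min(grid) - rng$alpha_min), 0.01 + 1e-9)
      expect_lt(abs(max(grid) - rng$alpha_max), 0.01 + 1e-9)
      expect_true(rng$alpha_min <= rng$alpha_opt + 1e-9 &&
                    rng$alpha_opt <= rng$alpha_max + 1e-9)
    }
  }
})

test_that("offsets are the mode of CE-minus-GBS differences", {
  gbs <- reference_from_pairs(list(A = c(181, 185), B = c(181, 189),
                                   C = c(185, 185)))
  ce_minus3 <- reference_from_pairs(list(A = c(178, 182), B = c(178, 186),
                                         C = c(182, 182)))
  off <- estimate_size_offsets(gbs, ce_minus3)
  expect_equal(off$ce_offset, -3L)

  expect_equal(estimate_size_offsets(gbs, gbs)$ce_offset, 0L)

  # CE = GBS - 4 recovers -4
  ce4 <- dplyr::mutate(gbs, allele_a = allele_a - 4L, allele_b = allele_b - 4L)
  expect_equal(estimate_size_offsets(gbs, ce4)$ce_offset, -4L)
})

test_that("offset estimation is translation-equivariant", {
  withr::local_seed(41)
  gbs <- reference_from_pairs(list(A = c(150, 154), B = c(150, 158),
                                   C = c(154, 158), D = c(158, 158)))
  ce <- dplyr::mutate(gbs, allele_a = allele_a + 2L, allele_b = allele_b + 2L)
  base <- estimate_size_offsets(gbs, ce)$ce_offset
  for (k in c(-5L, -1L, 3L)) {
    shifted <- dplyr::mutate(gbs, allele_a = allele_a + k,
                             allele_b = allele_b + k)
    expect_equal(estimate_size_offsets(shifted, ce)$ce_offset, base - k)
  }
})

test_that("allele dropout is flagged when a CE allele misses the top-4 profile", {
  profiles <- profiles_from_counts(
    JM1 = c(`170` = 970, `167` = 20, `173` = 7, `164` = 3),
    OK1 = c(`170` = 500, `182` = 480, `167` = 20)
  )
  reference <- reference_from_pairs(list(JM1 = c(170, 182),
                                         OK1 = c(170, 182)))
  offsets <- tibble::tibble(marker = "MK1", ce_offset = 0L)
  drop <- detect_allele_dropout(profiles, reference, offsets)
  expect_equal(nrow(drop), 1)
  expect_equal(drop$variety, "JM1")
  expect_equal(drop$ce_allele, 182L)

  # perfect concordance yields an empty list
  ref_ok <- reference_from_pairs(list(OK1 = c(170, 182)))
  expect_equal(nrow(detect_allele_dropout(profiles, ref_ok, offsets)), 0)
})

test_that("marker classification follows the documented precedence", {
  expect_equal(classify_marker(14, 0, TRUE), "low_depth")
  expect_equal(classify_marker(2442, 4, TRUE), "dropout")
  expect_equal(classify_marker(2442, 4, FALSE, "stutter"), "dropout")
  expect_equal(classify_marker(6834, 0, FALSE, "stutter"), "stutter_error")
  expect_equal(classify_marker(3611, 0, TRUE), "suitable")
  expect_equal(classify_marker(50, 0, TRUE), "suitable")   # boundary: keep at 50
  expect_equal(classify_marker(49.9, 0, TRUE), "low_depth")
})

test_that("repeatability is the Pearson correlation of first-allele frequencies", {
  p1 <- profiles_from_counts(A = c(`100` = 90, `96` = 10),
                             B = c(`100` = 55, `104` = 45),
                             C = c(`100` = 70, `104` = 30))
  expect_equal(replicate_repeatability(p1, p1)$correlation, 1)

  # adding a constant to f1 leaves the correlation at 1
  p2 <- profiles_from_counts(A = c(`100` = 92, `96` = 8),
                             B = c(`100` = 57, `104` = 43),
                             C = c(`100` = 72, `104` = 28))
  expect_equal(replicate_repeatability(p1, p2)$correlation, 1)

  expect_error(replicate_repeatability(p1[p1$variety != "C", ], p2),
               "fewer than 3")
})

test_that("full calibration assembles offsets, intervals, dropout and classes", {
  profiles <- dplyr::bind_rows(
    profiles_from_counts(
      H1 = c(`100` = 53, `104` = 46, `96` = 1),
      O1 = c(`100` = 95, `96` = 5),
      marker = "MK1"
    ),
    profiles_from_counts(
      H1 = c(`200` = 55, `208` = 44, `196` = 1),
      O1 = c(`208` = 97, `204` = 3),
      marker = "MK2"
    )
  )
  reference <- dplyr::bind_rows(
    reference_from_pairs(list(H1 = c(102, 106), O1 = c(102, 102)),
                         marker = "MK1"),
    reference_from_pairs(list(H1 = c(199, 207), O1 = c(207, 207)),
                         marker = "MK2")
  )
  cal <- calibrate_markers(profiles, reference, tiny_panel())
  expect_s3_class(cal, "ssr_calibration")
  expect_equal(cal$ce_offset, c(2L, -1L))
  expect_equal(cal$classification, c("suitable", "suitable"))
  expect_equal(cal$alpha_min, c(0.53, 0.55))
  expect_equal(cal$alpha_max, c(0.95, 0.97))

  g <- glance(cal)
  expect_equal(g$n_suitable, 2)
  td <- tidy(cal)
  expect_type(td$dropout_varieties, "character")

  pan <- calibrated_panel(tiny_panel(), cal)
  expect_equal(pan$alpha, cal$alpha_opt)
  expect_equal(pan$ce_offset, cal$ce_offset)
})
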