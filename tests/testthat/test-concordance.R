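reg <- toy_registry()
thr <- reg$thresholds

# small helper: CE calls + MPS calls for one sample at one locus
pair_calls <- function(ce_alleles, ce_heights, sequences, reads,
                       locus = "TOYA") {
  list(
    ce = call_ce_profiles(toy_peaks(ce_alleles, ce_heights, locus), reg),
    mps = call_mps_profiles(toy_records(sequences, reads, locus), reg)
  )
}

test_that("identical allele sets are concordant", {
  pc <- pair_calls("13", 900, strrep("TCTA", 13), 700)
  cc <- compare_calls(pc$ce, pc$mps, reg, loci = "TOYA")
  expect_equal(cc$status, "concordant")
  expect_equal(cc$ce_alleles, "13")
  expect_equal(cc$mps_alleles, "13")
})

test_that("a CE-only allele matching an MPS grey-zone candidate is an
           apparent discordance, not a true one", {
  pc <- pair_calls(
    c("14", "19"), c(900, 800),
    c(strrep("GAAA", 14), strrep("GAAA", 19), strrep("GAAA", 13)),
    c(280, 19, 28),
    locus = "TOYM"
  )
  cc <- compare_calls(pc$ce, pc$mps, reg, loci = "TOYM")
  expect_equal(cc$status, "apparent_discordant_grey_zone")
  expect_match(cc$notes, "19")
  # a near miss (grey-zone candidate of a different length) stays
  # discordant
  pc2 <- pair_calls(
    c("14", "19"), c(900, 800),
    c(strrep("GAAA", 14), strrep("GAAA", 18), strrep("GAAA", 13)),
    c(280, 19, 28),
    locus = "TOYM"
  )
  cc2 <- compare_calls(pc2$ce, pc2$mps, reg, loci = "TOYM")
  expect_equal(cc2$status, "discordant")
})

test_that("an inconclusive MPS locus is excluded regardless of CE", {
  pc <- pair_calls(
    "13", 900,
    c(strrep("TCTA", 13), strrep("TCTA", 12)), c(12, 4)
  )
  cc <- compare_calls(pc$ce, pc$mps, reg, loci = "TOYA")
  expect_equal(cc$status, "excluded_inconclusive")
})

test_that("duplication and deletion patterns are concordant when both
           platforms agree", {
  # two alleles at a single-copy locus on both sides
  pc <- pair_calls(
    c("15", "16"), c(900, 850),
    c(strrep("TCTA", 15), strrep("TCTA", 16)), c(400, 380)
  )
  cc <- compare_calls(pc$ce, pc$mps, reg, loci = "TOYA")
  expect_equal(cc$status, "concordant")
  expect_match(cc$notes, "duplication")
  # nothing on either platform: deletion
  ce_empty <- call_ce_profiles(toy_peaks("13", 900, "TOYM"), reg)
  mps_empty <- call_mps_profiles(
    toy_records(strrep("GAAA", 14), 500, "TOYM"), reg
  )
  cc2 <- compare_calls(ce_empty, mps_empty, reg,
    loci = "TOYA", samples = "S1"
  )
  expect_equal(cc2$status, "concordant")
  expect_match(cc2$notes, "deletion")
  # platforms disagreeing on the pattern are discordant
  pc3 <- pair_calls(
    c("15", "16"), c(900, 850),
    strrep("TCTA", 15), 400
  )
  cc3 <- compare_calls(pc3$ce, pc3$mps, reg, loci = "TOYA")
  expect_equal(cc3$status, "discordant")
})

test_that("comparison is reflexive: equal sets from either side are
           concordant whatever the platform provenance", {
  pc <- pair_calls(
    c("10", "12"), c(900, 800),
    c(strrep("TCTA", 10), strrep("TCTA", 12)), c(400, 350)
  )
  cc <- compare_calls(pc$ce, pc$mps, reg, loci = "TOYA")
  expect_equal(cc$status, "concordant")
})

test_that("the allele census deduplicates lengths and counts variant
           sequences once per locus", {
  seqs <- c(
    rep(strrep("TCTA", 11), 2),
    paste0(strrep("TCTA", 5), "TCTG", strrep("TCTA", 5))
  )
  mps <- call_mps_profiles(
    dplyr::bind_rows(
      toy_records(seqs[1], 700, sample = "S1"),
      toy_records(seqs[2], 650, sample = "S2"),
      toy_records(seqs[3], 600, sample = "S3")
    ),
    reg
  )
  ce <- call_ce_profiles(
    dplyr::bind_rows(
      toy_peaks("11", 900, sample = "S1"),
      toy_peaks("11", 880, sample = "S2"),
      toy_peaks("11", 860, sample = "S3")
    ),
    reg
  )
  cen <- census_alleles(ce, mps)
  expect_equal(cen$n_length_alleles, 1)
  expect_equal(cen$n_sequence_additional, 1)
  # CE-only census has no sequence additions
  cen_ce <- census_alleles(ce, NULL)
  expect_equal(cen_ce$n_sequence_additional, 0)
  # empty dataset: empty census
  empty <- census_alleles(
    ce[0, ], mps[0, ]
  )
  expect_equal(nrow(empty), 0)
})

test_that("census totals add up: length + additions = unique (locus,
           sequence) pairs when every sequence is known", {
  sr <- study_run()
  called <- sr$res$mps_calls |> dplyr::filter(status == "called")
  cen <- census_alleles(
    sr$res$ce_calls[0, ], sr$res$mps_calls
  )
  per_locus <- called |>
    dplyr::group_by(locus) |>
    dplyr::summarise(
      n_len = dplyr::n_distinct(allele),
      n_seq = dplyr::n_distinct(sequence)
    )
  joined <- dplyr::left_join(cen, per_locus, by = "locus")
  # every extra unique sequence beyond one per length allele is variant
  # or iso; with reference sequences shared, additions = n_seq - n_len
  # whenever each length has one reference representative
  expect_true(all(
    joined$n_length_alleles + joined$n_sequence_additional <= joined$n_seq |
      is.na(joined$n_seq)
  ))
  expect_equal(joined$n_length_alleles, joined$n_len)
})

test_that("intra-locus balance follows the minor/major definition and
           platform thresholds", {
  mps <- call_mps_profiles(
    toy_records(
      c(strrep("GAAA", 14), strrep("GAAA", 16)), c(280, 218),
      locus = "TOYM"
    ),
    reg
  )
  bal <- compute_balance(mps, reg, "MPS")
  expect_equal(round(bal$ilb_pct, 2), 77.86)
  expect_false(bal$below_threshold) # 77.9% > 60%
  ce <- call_ce_profiles(
    toy_peaks(c("14", "16"), c(500, 500), locus = "TOYM"), reg
  )
  bal_ce <- compute_balance(ce, reg, "CE")
  expect_equal(bal_ce$ilb_pct, 100)
  # below-threshold flag uses the platform-specific cutoffs
  mps_low <- call_mps_profiles(
    toy_records(
      c(strrep("GAAA", 14), strrep("GAAA", 16)), c(500, 250),
      locus = "TOYM"
    ),
    reg
  )
  expect_true(compute_balance(mps_low, reg, "MPS")$below_threshold)
})

test_that("tri-allelic genotypes are excluded from balance with a log", {
  mps <- call_mps_profiles(
    toy_records(
      c(strrep("GAAA", 37), strrep("GAAA", 38), strrep("GAAA", 39)),
      c(300, 280, 260),
      locus = "TOYM"
    ),
    reg
  )
  bal <- compute_balance(mps, reg, "MPS")
  expect_equal(nrow(bal), 0)
  excl <- attr(bal, "exclusions")
  expect_equal(nrow(excl), 1)
  expect_match(excl$reason, "tri-allelic")
})

test_that("the pooled t-test matches the hand-computed example and the
           stats oracle", {
  r <- students_t(c(10, 12, 14), c(11, 13, 15))
  expect_equal(round(r$statistic, 4), -0.6124)
  expect_equal(r$parameter, 4)
  # cross-check against the independent implementation
  ht <- stats::t.test(c(10, 12, 14), c(11, 13, 15), var.equal = TRUE)
  expect_equal(r$statistic, unname(ht$statistic), tolerance = 1e-12)
  expect_equal(r$p.value, ht$p.value, tolerance = 1e-12)
  expect_equal(r$conf.low, ht$conf.int[1], tolerance = 1e-12)
  expect_equal(r$conf.high, ht$conf.int[2], tolerance = 1e-12)
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(sample(3:20, 1), 10, 2)
    y <- rnorm(sample(3:20, 1), 11, 3)
    mine <- students_t(x, y)
    ref <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
  }
  # Welch variant delegates correctly
  w <- students_t(c(1, 2, 3, 9), c(2, 4, 8), var_equal = FALSE)
  wr <- stats::t.test(c(1, 2, 3, 9), c(2, 4, 8))
  expect_equal(w$statistic, unname(wr$statistic), tolerance = 1e-10)
})

test_that("degenerate t-test inputs behave as defined", {
  r <- students_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  # both groups constant and equal
  r2 <- students_t(c(5, 5), c(5, 5))
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p.value, 1)
  # constant but different
  r3 <- students_t(c(5, 5), c(7, 7))
  expect_equal(r3$statistic, -Inf)
  expect_equal(r3$p.value, 0)
  expect_error(students_t(5, c(1, 2)), "at least two")
})

test_that("stutter summaries drop excluded observations and report the
           filter exceedances", {
  obs <- dplyr::tibble(
    sample_id = c("S1", "S2", "S3", "S1"),
    locus = "TOYA", platform = "CE",
    parent_allele = "11", parent_copy = NA_character_,
    stutter_type = "minus_one_repeat", stutter_allele = "10",
    signal = c(100, 120, 140, 999), parent_signal = 1000,
    ratio_pct = c(10, 12, 14, 99.9),
    excluded = c(FALSE, FALSE, FALSE, TRUE),
    exclusion_reason = c("none", "none", "none", "overlaps_smaller_allele"),
    note = NA_character_
  )
  s <- summarize_stutters(obs, reg)
  expect_equal(s$n, 3)
  expect_equal(s$mean_pct, 12)
  expect_equal(s$min_pct, 10)
  expect_equal(s$max_pct, 14)
  expect_equal(s$n_above_filter, 0) # filter is 15%
  # removing the exclusion shifts the mean (oracle: recompute by hand)
  obs2 <- obs
  obs2$excluded <- FALSE
  s2 <- summarize_stutters(obs2, reg)
  expect_equal(s2$mean_pct, mean(c(10, 12, 14, 99.9)))
  # no observations at all: zero-row summary
  expect_equal(nrow(summarize_stutters(obs[0, ], reg)), 0)
})

test_that("per-locus stutter t-tests compare CE with MPS", {
  obs <- dplyr::bind_rows(
    dplyr::tibble(
      sample_id = paste0("S", 1:4), locus = "TOYA", platform = "CE",
      parent_allele = "11", parent_copy = NA_character_,
      stutter_type = "minus_one_repeat", stutter_allele = "10",
      signal = 1, parent_signal = 10, ratio_pct = c(10, 11, 12, 13),
      excluded = FALSE, exclusion_reason = "none", note = NA_character_
    ),
    dplyr::tibble(
      sample_id = paste0("S", 1:4), locus = "TOYA", platform = "MPS",
      parent_allele = "11", parent_copy = NA_character_,
      stutter_type = "minus_one_repeat", stutter_allele = "10",
      signal = 1, parent_signal = 10, ratio_pct = c(14, 15, 16, 17),
      excluded = FALSE, exclusion_reason = "none", note = NA_character_
    )
  )
  tt <- stutter_tests(obs)
  expect_equal(nrow(tt), 1)
  ref <- stats::t.test(c(10, 11, 12, 13), c(14, 15, 16, 17),
    var.equal = TRUE
  )
  expect_equal(tt$statistic, unname(ref$statistic), tolerance = 1e-10)
})
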