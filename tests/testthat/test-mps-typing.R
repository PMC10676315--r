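test_that("the 85,000-read sample gate is inclusive at the boundary", {
  thr <- threshold_config()
  g <- gate_samples(
    dplyr::tibble(
      sample_id = c("A", "B", "C"),
      total_reads = c(93000, 85000, 84999)
    ),
    thr
  )
  expect_equal(g$pass, c(TRUE, TRUE, FALSE))
})

test_that("AT/IT recalculation reproduces the documented read floors", {
  expect_equal(recalc_thresholds(650)$at_reads, 10) # ceil(9.75)
  expect_equal(recalc_thresholds(650)$it_reads, 30) # ceil(29.25)
  # below the 650-read basis the floors persist
  expect_equal(recalc_thresholds(200)$at_reads, 10)
  expect_equal(recalc_thresholds(200)$it_reads, 30)
  # above it the percentages scale
  expect_equal(recalc_thresholds(2000)$at_reads, 30)
  expect_equal(recalc_thresholds(2000)$it_reads, 90)
  # both admissible readings agree at and below the basis
  h <- recalc_thresholds(400, method = "hard_floor")
  expect_equal(c(h$at_reads, h$it_reads), c(10, 30))
  # AT < IT for arbitrary inputs and both methods
  set.seed(3)
  reads <- c(0, sample(1:20000, 50))
  for (m in c("basis_floor", "hard_floor")) {
    t <- recalc_thresholds(reads, method = m)
    expect_true(all(t$at_reads < t$it_reads))
  }
  expect_true(all(recalc_thresholds(0:650)$at_reads == 10))
  expect_true(all(recalc_thresholds(0:650)$it_reads == 30))
})

test_that("grey-zone candidates are surfaced but never auto-called", {
  reg <- toy_registry()
  ld <- toy_locus("TOYA")
  thr <- reg$thresholds
  # 19 reads against thresholds (10, 30): a grey-zone candidate
  rec <- toy_records(
    c(strrep("TCTA", 11), strrep("TCTA", 14)), c(280, 19)
  )
  call <- call_mps_locus(rec, ld, thr)
  expect_equal(call$status[call$allele == "14"], "grey_zone")
  expect_equal(call$status[call$allele == "11"], "called")
  expect_true(grepl("grey_zone", call$qc_flags[1]))
  # at exactly the interpretation threshold the allele is called
  rec30 <- toy_records(
    c(strrep("TCTA", 11), strrep("TCTA", 14)), c(280, 30)
  )
  call30 <- call_mps_locus(rec30, ld, thr)
  expect_equal(call30$status[call30$allele == "14"], "called")
  # at exactly the analytical threshold the record is discarded (the
  # grey zone requires exceeding AT)
  rec10 <- toy_records(
    c(strrep("TCTA", 11), strrep("TCTA", 14)), c(280, 10)
  )
  call10 <- call_mps_locus(rec10, ld, thr)
  expect_equal(call10$status[call10$allele == "14"], "discarded")
})

test_that("a locus where nothing reaches IT is flagged inconclusive", {
  ld <- toy_locus("TOYA")
  call <- call_mps_locus(
    toy_records(c(strrep("TCTA", 11), strrep("TCTA", 10)), c(8, 5)),
    ld, toy_registry()$thresholds
  )
  expect_equal(sum(call$status == "called"), 0)
  expect_true(all(grepl("low_coverage_inc", call$qc_flags)))
})

test_that("sequence-exact stutters are attributed, within the filter only", {
  ld <- toy_locus("TOYA")
  thr <- toy_registry()$thresholds
  parent <- strrep("TCTA", 11)
  # 12% of parent at n-1: stutter (filter 20%)
  call <- call_mps_locus(
    toy_records(c(parent, strrep("TCTA", 10)), c(800, 96)), ld, thr
  )
  expect_equal(call$status[call$allele == "10"], "stutter")
  expect_equal(call$stutter_of[call$allele == "10"], "11")
  # 40% of parent at n-1: exceeds the filter, called as a second allele
  call2 <- call_mps_locus(
    toy_records(c(parent, strrep("TCTA", 10)), c(800, 320)), ld, thr
  )
  expect_equal(call2$status[call2$allele == "10"], "called")
  # a one-repeat-shorter *variant* string is not the parent's stutter
  var10 <- paste0(strrep("TCTA", 4), "TCTG", strrep("TCTA", 5))
  call3 <- call_mps_locus(
    toy_records(c(parent, var10), c(800, 96)), ld, thr
  )
  expect_equal(call3$status[call3$allele == "10"], "called")
})

test_that("MPS stutter observations use the read-ratio definition", {
  reg <- toy_registry()
  parent <- strrep("TCTA", 11)
  recs <- toy_records(
    c(parent, strrep("TCTA", 10), strrep("TCTA", 12)),
    c(800, 96, 40)
  )
  calls <- call_mps_profiles(recs, reg)
  obs <- collect_mps_stutters(calls, reg)
  expect_equal(nrow(obs), 2)
  minus <- obs[obs$stutter_type == "minus_one_repeat", ]
  expect_equal(minus$ratio_pct, 12)
  plus <- obs[obs$stutter_type == "plus_one_repeat", ]
  expect_equal(plus$ratio_pct, 5)
})

test_that("adjacent multicopy alleles exclude the overlapped stutter
           directions", {
  reg <- toy_registry()
  recs <- toy_records(
    c(strrep("GAAA", 15), strrep("GAAA", 14), strrep("GAAA", 13)),
    c(500, 420, 60),
    locus = "TOYM"
  )
  calls <- call_mps_profiles(recs, reg)
  # 14 and 15 both called; 13 is the (shared-position) n-1 stutter of 14
  expect_setequal(
    calls$allele[calls$status == "called"], c("14", "15")
  )
  obs <- collect_mps_stutters(calls, reg)
  minus15 <- obs[obs$parent_allele == "15" &
    obs$stutter_type == "minus_one_repeat", ]
  expect_true(all(minus15$excluded))
  expect_true(all(minus15$exclusion_reason == "overlaps_smaller_allele"))
  plus14 <- obs[obs$parent_allele == "14" &
    obs$stutter_type == "plus_one_repeat", ]
  expect_true(all(plus14$excluded))
  minus14 <- obs[obs$parent_allele == "14" &
    obs$stutter_type == "minus_one_repeat", ]
  expect_false(any(minus14$excluded))
})

test_that("iso-alleles and variant homozygotes are reported at multicopy
           loci", {
  reg <- toy_registry()
  seq_ref <- strrep("GAAA", 14)
  seq_var <- paste0(strrep("GAAA", 7), "GGAA", strrep("GAAA", 6))
  # same length, different sequences: an iso-allele pair
  calls <- call_mps_profiles(
    toy_records(c(seq_ref, seq_var), c(400, 380), locus = "TOYM"),
    reg
  )
  iso <- detect_iso_alleles(calls, reg)
  expect_equal(iso$category, "iso_allele_pair")
  expect_equal(iso$allele, "14")
  # different lengths: no report
  calls2 <- call_mps_profiles(
    toy_records(c(seq_ref, strrep("GAAA", 15)), c(400, 380),
      locus = "TOYM"
    ),
    reg
  )
  expect_equal(nrow(detect_iso_alleles(calls2, reg)), 0)
  # one called variant sequence: variant homozygote
  calls3 <- call_mps_profiles(
    toy_records(seq_var, 700, locus = "TOYM"), reg
  )
  iso3 <- detect_iso_alleles(calls3, reg)
  expect_equal(iso3$category, "variant_homozygote")
})

test_that("parse_mps_table validates reads and sequence alphabet", {
  txt <- paste(
    "sample_id\tlocus\tsequence\treads\ttyped_flag",
    "S1\tTOYA\tTCTATCTA\t100\tYES",
    "S1\tTOYA\tTCTN\t50\tNO",
    "S1\tTOYA\tTCTA\t0\tNO",
    sep = "\n"
  )
  expect_warning(tbl <- parse_mps_table(I(txt)), "rejected")
  expect_equal(nrow(tbl), 1)
  expect_equal(nrow(attr(tbl, "rejects")), 2)
})
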