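test_that("parse_ce_table rejects malformed rows without dropping them
           silently", {
  txt <- paste(
    "sample_id\tlocus\tallele\tsize_bp\theight_rfu\tdye",
    "S1\tTOYA\t11\t144\t1000\tFAM",
    "S1\tTOYA\t10\t140\t-5\tFAM",
    "S1\tTOYA\txx\t140\t500\tFAM",
    sep = "\n"
  )
  expect_warning(tbl <- parse_ce_table(I(txt)), "rejected")
  expect_equal(nrow(tbl), 1)
  rej <- attr(tbl, "rejects")
  expect_equal(nrow(rej), 2)
  expect_setequal(
    rej$reject_reason,
    c("non-positive height", "unparseable allele label")
  )
  # empty file with header parses to an empty table
  hdr <- "sample_id\tlocus\tallele\tsize_bp\theight_rfu\tdye\n"
  expect_equal(nrow(parse_ce_table(I(hdr))), 0)
  # missing required column is a format error (readr also warns about
  # the absent parsers; the error is what matters)
  expect_error(
    suppressWarnings(parse_ce_table(I("sample_id\tlocus\tallele\n"))),
    "missing required columns"
  )
})

test_that("CE calling applies PAT, stutter filter and 100/200 RFU minima", {
  ld <- toy_locus("TOYA")
  thr <- threshold_config()
  # lone 190 RFU peak: above PAT but below the 200 RFU homozygous minimum
  c1 <- call_ce_locus(toy_peaks(11, 190), ld, thr)
  expect_equal(c1$zygosity, "no_call")
  expect_equal(c1$filter_reason, "below_hom")
  # 240/2000 one repeat apart = 12% <= 15% filter: stutter (both peaks
  # sit above the 175 RFU PAT, which applies first)
  c2 <- call_ce_locus(toy_peaks(c(11, 10), c(2000, 240)), ld, thr)
  expect_equal(c2$status[c2$allele == "11"], "called")
  expect_equal(c2$filter_reason[c2$allele == "10"], "stutter_filtered")
  expect_equal(c2$zygosity, rep("single_peak", 2))
  # 600/2000 = 30% > filter: two called alleles
  c3 <- call_ce_locus(toy_peaks(c(11, 10), c(2000, 600)), ld, thr)
  expect_equal(sum(c3$status == "called"), 2)
  expect_equal(unique(c3$zygosity), "heterozygous")
  # below-PAT peaks never reach the caller logic
  c4 <- call_ce_locus(toy_peaks(c(11, 10), c(1000, 150)), ld, thr)
  expect_equal(c4$filter_reason[c4$allele == "10"], "below_pat")
  # 18% ratio is above the 15% filter: the peak is a real second allele
  c5 <- call_ce_locus(toy_peaks(c(11, 10), c(1000, 180)), ld, thr)
  expect_equal(c5$status[c5$allele == "10"], "called")
  # with a lowered PAT, a surviving non-stutter peak under 100 RFU is
  # filtered by the heterozygous minimum
  thr_low <- threshold_config(pat_rfu = 50)
  c6 <- call_ce_locus(toy_peaks(c(11, 8), c(1000, 80)), ld, thr_low)
  expect_equal(c6$filter_reason[c6$allele == "8"], "below_het")
})

test_that("every peak is either called or filtered with exactly one reason", {
  sr <- study_run()
  calls <- sr$res$ce_calls
  expect_true(all(calls$status %in% c("called", "filtered")))
  expect_true(all(is.na(calls$filter_reason[calls$status == "called"])))
  expect_true(all(!is.na(calls$filter_reason[calls$status == "filtered"])))
  expect_true(all(calls$filter_reason %in%
    c(NA, "below_pat", "stutter_filtered", "below_het", "below_hom")))
})

test_that("raising the PAT never increases the number of called alleles", {
  reg <- toy_registry()
  set.seed(99)
  for (i in 1:25) {
    n <- sample(2:6, 1)
    peaks <- toy_peaks(
      sample(8:14, n), round(runif(n, 50, 3000)),
      locus = "TOYA"
    )
    called <- purrr::map_int(c(100, 175, 300, 600), function(pat) {
      thr <- threshold_config(pat_rfu = pat)
      sum(call_ce_locus(peaks, toy_locus("TOYA"), thr)$status == "called")
    })
    expect_true(all(diff(called) <= 0))
  }
})

test_that("CE stutter ratios are collected with the arithmetic definition", {
  reg <- toy_registry()
  calls <- call_ce_profiles(
    toy_peaks(c(11, 10), c(2000, 240)), reg
  )
  obs <- collect_ce_stutters(calls, reg)
  expect_equal(nrow(obs), 1)
  expect_equal(obs$stutter_type, "minus_one_repeat")
  expect_equal(obs$ratio_pct, 12)
  expect_false(obs$excluded)
})

test_that("adjacent multicopy alleles trigger the overlap exclusions", {
  reg <- toy_registry()
  # alleles 14 and 15 at a multicopy locus, plus a clean n-1 stutter of 14
  peaks <- toy_peaks(
    c(13, 14, 15), c(260, 2200, 2000),
    locus = "TOYM"
  )
  calls <- call_ce_profiles(peaks, reg)
  obs <- collect_ce_stutters(calls, reg)
  minus15 <- obs[obs$parent_allele == "15" &
    obs$stutter_type == "minus_one_repeat", ]
  expect_true(minus15$excluded)
  expect_equal(minus15$exclusion_reason, "overlaps_smaller_allele")
  plus14 <- obs[obs$parent_allele == "14" &
    obs$stutter_type == "plus_one_repeat", ]
  expect_true(plus14$excluded)
  expect_equal(plus14$exclusion_reason, "overlaps_larger_allele")
  minus14 <- obs[obs$parent_allele == "14" &
    obs$stutter_type == "minus_one_repeat", ]
  expect_false(minus14$excluded)
  expect_equal(minus14$ratio_pct, 260 / 2200 * 100)
  # gap > 1 repeat: no exclusions anywhere
  peaks2 <- toy_peaks(c(14, 19, 13, 18), c(2000, 1800, 300, 270),
    locus = "TOYM"
  )
  obs2 <- collect_ce_stutters(call_ce_profiles(peaks2, reg), reg)
  expect_true(all(!obs2$excluded))
  expect_equal(nrow(obs2), 2)
})

test_that("a peak between two called alleles takes the minus
           interpretation, flagged ambiguous", {
  reg <- toy_registry()
  peaks <- toy_peaks(c(12, 13, 14), c(1000, 60, 900), locus = "TOYA")
  thr <- threshold_config(pat_rfu = 50)
  calls <- call_ce_profiles(peaks, reg, thr)
  obs <- collect_ce_stutters(calls, reg)
  mid <- obs[obs$stutter_allele == "13", ]
  expect_equal(mid$stutter_type, "minus_one_repeat")
  expect_equal(mid$parent_allele, "14")
  expect_equal(mid$note, "ambiguous")
})

test_that("unknown loci are a hard error", {
  reg <- toy_registry()
  expect_error(
    call_ce_profiles(toy_peaks(11, 1000, locus = "NOPE"), reg),
    "NOPE"
  )
})
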