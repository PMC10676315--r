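#' Run the full CE-vs-MPS concordance analysis
#'
#' End-to-end pipeline: gates MPS samples on the total-read threshold,
#' calls genotypes on both platforms, classifies per sample x locus
#' concordance, collects and summarises stutter observations, computes
#' multicopy intra-locus balance with per-locus CE-vs-MPS t-tests, and
#' takes the allele census.
#'
#' @param ce_peaks CE peak tibble ([parse_ce_table()] or the simulator).
#' @param mps_reads MPS read tibble ([parse_mps_table()] or the
#'   simulator).
#' @param registry An `ystr_registry` (default [default_registry()]).
#' @param mps_sample_totals Optional tibble `sample_id`, `total_reads`
#'   for the 85,000-read sample gate; when omitted the gate is skipped
#'   (the per-locus table does not carry whole-panel totals).
#' @param include_unanalyzed Compare all registry loci instead of only
#'   those flagged analyzed on both platforms.
#' @param recalc_method AT/IT recalculation rule, see
#'   [recalc_thresholds()].
#' @param var_equal Use the pooled-variance Student t-test (`TRUE`,
#'   default) or Welch's test for the platform comparisons.
#' @return An object of class `ystr_concordance`: a list of tibbles
#'   (`concordance`, `ce_calls`, `mps_calls`, `stutters`,
#'   `stutter_summary`, `stutter_tests`, `balance`, `balance_tests`,
#'   `census`, `iso_alleles`, `gated_out`) plus run metadata. Has
#'   [tidy()], [glance()] and [autoplot()] methods.
#' @export
ystr_concordance <- function(ce_peaks, mps_reads,
                             registry = default_registry(),
                             mps_sample_totals = NULL,
                             include_unanalyzed = FALSE,
                             recalc_method = "basis_floor",
                             var_equal = TRUE) {
  check_known_loci(ce_peaks$locus, registry)
  check_known_loci(mps_reads$locus, registry)
  thresholds <- registry$thresholds

  gated_out <- tibble(sample_id = character(), total_reads = numeric())
  if (!is.null(mps_sample_totals)) {
    gate <- gate_samples(mps_sample_totals, thresholds)
    gated_out <- gate |>
      filter(!.data$pass) |>
      select("sample_id", "total_reads")
    mps_reads <- mps_reads |>
      filter(!.data$sample_id %in% gated_out$sample_id)
  }

  ce_calls <- call_ce_profiles(ce_peaks, registry, thresholds)
  mps_calls <- if (nrow(mps_reads)) {
    call_mps_profiles(mps_reads, registry, thresholds, recalc_method)
  } else {
    tibble(
      sample_id = character(), locus = character(), sequence = character(),
      reads = numeric(), typed_flag = character(), bracket = character(),
      allele = character(), repeats = integer(), partial_nt = integer(),
      is_variant = logical(), locus_reads = numeric(), at_reads = numeric(),
      it_reads = numeric(), status = character(), stutter_of = character(),
      copy = character(), qc_flags = character()
    )
  }

  loci <- if (include_unanalyzed) {
    names(registry$loci)
  } else {
    analyzed_loci(registry, "both")
  }
  concordance <- compare_calls(ce_calls, mps_calls, registry, loci = loci)

  stutters <- bind_rows(
    collect_ce_stutters(ce_calls, registry),
    collect_mps_stutters(mps_calls, registry)
  )
  parents <- bind_rows(
    ce_calls |>
      filter(.data$status == "called") |>
      distinct(.data$sample_id, .data$locus) |>
      mutate(platform = "CE"),
    mps_calls |>
      filter(.data$status == "called") |>
      distinct(.data$sample_id, .data$locus) |>
      mutate(platform = "MPS")
  )
  stutter_summary <- summarize_stutters(stutters, registry, parents)
  stutter_tst <- stutter_tests(stutters, var_equal = var_equal)

  bal_ce <- compute_balance(ce_calls, registry, "CE", thresholds)
  bal_mps <- compute_balance(mps_calls, registry, "MPS", thresholds)
  balance <- bind_rows(bal_ce, bal_mps)
  balance_excl <- bind_rows(
    attr(bal_ce, "exclusions") |> mutate(platform = "CE"),
    attr(bal_mps, "exclusions") |> mutate(platform = "MPS")
  )
  balance_tests <- balance |>
    group_by(.data$locus) |>
    group_modify(function(g, key) {
      x <- g$ilb_pct[g$platform == "CE"]
      y <- g$ilb_pct[g$platform == "MPS"]
      if (length(x) < 2 || length(y) < 2) {
        return(tibble())
      }
      students_t(x, y, var_equal = var_equal)
    }) |>
    ungroup()

  census <- census_alleles(ce_calls, mps_calls)
  iso <- detect_iso_alleles(mps_calls, registry)

  structure(list(
    concordance = concordance,
    ce_calls = ce_calls,
    mps_calls = mps_calls,
    stutters = stutters,
    stutter_summary = stutter_summary,
    stutter_tests = stutter_tst,
    balance = balance,
    balance_exclusions = balance_excl,
    balance_tests = balance_tests,
    census = census,
    iso_alleles = iso,
    gated_out = gated_out,
    loci = loci,
    recalc_method = recalc_method,
    var_equal = var_equal
  ), class = "ystr_concordance")
}

#' @exportS3Method generics::tidy
tidy.ystr_concordance <- function(x, ...) x$concordance

#' @exportS3Method generics::glance
glance.ystr_concordance <- function(x, ...) {
  st <- x$concordance$status
  tibble(
    n_samples = n_distinct(x$concordance$sample_id),
    n_loci = length(x$loci),
    n_comparisons = length(st),
    n_concordant = sum(st == "concordant"),
    n_discordant = sum(st == "discordant"),
    n_grey_zone = sum(st == "apparent_discordant_grey_zone"),
    n_inconclusive = sum(st == "excluded_inconclusive"),
    pct_concordant = 100 * sum(st == "concordant") / max(length(st), 1),
    n_length_alleles = sum(x$census$n_length_alleles),
    n_sequence_additional = sum(x$census$n_sequence_additional),
    n_samples_gated_out = nrow(x$gated_out)
  )
}

#' @export
print.ystr_concordance <- function(x, ...) {
  g <- glance(x)
  cat("<ystr_concordance>\n")
  cat(sprintf(
    "  %d samples x %d loci: %d concordant, %d grey-zone, %d inconclusive, %d discordant\n",
    g$n_samples, g$n_loci, g$n_concordant, g$n_grey_zone,
    g$n_inconclusive, g$n_discordant
  ))
  cat(sprintf(
    "  %d unique length-based alleles, %d additional sequence-based\n",
    g$n_length_alleles, g$n_sequence_additional
  ))
  flagged <- x$concordance |> filter(.data$status != "concordant")
  if (nrow(flagged)) {
    cat("  non-concordant records:\n")
    for (i in seq_len(nrow(flagged))) {
      cat(sprintf(
        "    %s %s: CE {%s} vs MPS {%s} -> %s\n",
        flagged$sample_id[i], flagged$locus[i], flagged$ce_alleles[i],
        flagged$mps_alleles[i], flagged$status[i]
      ))
    }
  }
  invisible(x)
}
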