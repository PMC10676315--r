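# Toy registry: small loci with simple motifs so expected values can be
# derived by hand, independent of the shipped locus definitions.
toy_registry <- function() {
  load_locus_registry(list(
    defaults = list(
      pat_rfu = 175, ce_het_rfu = 100, ce_hom_rfu = 200,
      mps_sample_read_gate = 85000, mps_recalc_basis_reads = 650,
      ilb_threshold_ce = 65, ilb_threshold_mps = 60,
      at_pct = 1.5, it_pct = 4.5
    ),
    loci = list(
      TOYA = list(
        copy_number = "single", repeat_unit_length = 4,
        motif_structure = list(
          list(motif = "TCTA", expandable = TRUE, ref_repeats = 11)
        ),
        ref_allele_range = c(8, 14),
        ce_minus_stutter_filter = 15, ce_plus_stutter_filter = 6,
        mps_stutter_filter = 20
      ),
      TOYM = list(
        copy_number = "multi", repeat_unit_length = 4,
        motif_structure = list(
          list(motif = "GAAA", expandable = TRUE, ref_repeats = 14)
        ),
        ref_allele_range = c(10, 20),
        ce_minus_stutter_filter = 16, ce_plus_stutter_filter = 6,
        mps_stutter_filter = 20
      ),
      TOYB = list(
        copy_number = "single", repeat_unit_length = 4,
        motif_structure = list(
          list(motif = "TCTG", expandable = FALSE, ref_repeats = 2),
          list(motif = "TCTA", expandable = TRUE, ref_repeats = 9)
        ),
        counted_blocks = c(1, 2),
        ref_allele_range = c(8, 15),
        ce_minus_stutter_filter = 15, mps_stutter_filter = 20
      ),
      TOYT = list(
        copy_number = "single", repeat_unit_length = 3,
        motif_structure = list(
          list(motif = "CTT", expandable = TRUE, ref_repeats = 20)
        ),
        ref_allele_range = c(17, 25),
        ce_minus_stutter_filter = 30, mps_stutter_filter = 45
      )
    )
  ))
}

toy_locus <- function(name = "TOYA") toy_registry()$loci[[name]]

# quick CE peak tibble for one sample x locus
toy_peaks <- function(alleles, heights, locus = "TOYA", sample = "S1") {
  tibble::tibble(
    sample_id = sample, locus = locus, allele = as.character(alleles),
    size_bp = 100 + as.numeric(alleles) * 4, height_rfu = heights,
    dye = "FAM"
  )
}

# quick MPS record tibble for one sample x locus
toy_records <- function(sequences, reads, locus = "TOYA", sample = "S1",
                        typed = NULL) {
  typed <- typed %||% c("YES", rep("NO", length(sequences) - 1))
  tibble::tibble(
    sample_id = sample, locus = locus, sequence = sequences,
    reads = reads, typed_flag = typed
  )
}

`%||%` <- rlang::`%||%`

# Shared large-scale fixtures, built once per test run. The study-scale run
# uses the default (all scenario injections on) conditions; the clean run
# switches every injection off.
.fixture_env <- new.env(parent = emptyenv())

study_run <- function() {
  if (is.null(.fixture_env$study)) {
    cfg <- simulation_config(n_samples = 125, seed = 101)
    sim <- simulate_paired_tables(cfg)
    res <- ystr_concordance(
      sim$ce, sim$mps_reads, cfg$registry,
      mps_sample_totals = sim$mps_samples, include_unanalyzed = TRUE
    )
    .fixture_env$study <- list(cfg = cfg, sim = sim, res = res)
  }
  .fixture_env$study
}

clean_run <- function() {
  if (is.null(.fixture_env$clean)) {
    cfg <- simulation_config(
      n_samples = 125, seed = 102,
      inject_grey_zone_dropout = FALSE, inject_triallelic = FALSE,
      inject_duplication = FALSE, inject_deletion = FALSE,
      inject_low_coverage_locus = FALSE
    )
    sim <- simulate_paired_tables(cfg)
    res <- ystr_concordance(
      sim$ce, sim$mps_reads, cfg$registry,
      mps_sample_totals = sim$mps_samples, include_unanalyzed = TRUE
    )
    .fixture_env$clean <- list(cfg = cfg, sim = sim, res = res)
  }
  .fixture_env$clean
}
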