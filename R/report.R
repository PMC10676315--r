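#' Simulate a paired dataset and write it to disk
#'
#' Runs the generator and writes the CE peak table, MPS read and
#' per-sample total tables and the ground-truth profile table as
#' tab-delimited files, plus a YAML run manifest recording the seed,
#' per-file record counts and any warnings.
#'
#' @param out_dir Output directory (created if needed).
#' @param config An [simulation_config()].
#' @param seed Optional seed overriding the config's.
#' @return The manifest (list), invisibly.
#' @export
run_simulate <- function(out_dir, config = simulation_config(), seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_paired_tables(config)
  paths <- list(
    ce = file.path(out_dir, "ce_peaks.tsv"),
    mps_reads = file.path(out_dir, "mps_reads.tsv"),
    mps_samples = file.path(out_dir, "mps_samples.tsv"),
    truth = file.path(out_dir, "truth_profiles.tsv")
  )
  readr::write_tsv(sim$ce, paths$ce)
  readr::write_tsv(sim$mps_reads, paths$mps_reads)
  readr::write_tsv(sim$mps_samples, paths$mps_samples)
  readr::write_tsv(sim$profiles, paths$truth)
  warnings <- character()
  if (config$n_samples == 0) {
    warnings <- c(warnings, "n_samples = 0: tables are empty")
  }
  manifest <- list(
    tool = "ystrconcord",
    version = as.character(packageVersion("ystrconcord")),
    command = "simulate",
    seed = config$seed,
    n_samples = config$n_samples,
    outputs = purrr::map(paths, normalizePath, mustWork = FALSE),
    counts = list(
      true_allele_rows = nrow(sim$profiles),
      ce_peaks = nrow(sim$ce),
      mps_records = nrow(sim$mps_reads),
      mps_samples = nrow(sim$mps_samples)
    ),
    warnings = as.list(warnings)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Run the concordance analysis from files and write the report set
#'
#' Parses the CE and MPS tables, runs [ystr_concordance()] and writes
#' the full report set: concordance records, stutter observations and
#' summaries with per-locus t-tests, intra-locus balance with t-tests,
#' allele census, iso-allele report, a plain-text summary naming every
#' non-concordant sample x locus, and a YAML manifest with record
#' counts for every stage.
#'
#' @param ce_path CE peak TSV.
#' @param mps_path MPS read TSV.
#' @param out_dir Output directory.
#' @param registry_path Optional registry YAML; the shipped default
#'   registry otherwise.
#' @param samples_path Optional per-sample total-read TSV for the
#'   sample gate.
#' @param t_test `"student"` (pooled) or `"welch"`.
#' @param recalc_method See [recalc_thresholds()].
#' @param include_unanalyzed Compare all registry loci.
#' @return The `ystr_concordance` result, invisibly.
#' @export
run_concordance <- function(ce_path, mps_path, out_dir,
                            registry_path = NULL, samples_path = NULL,
                            t_test = c("student", "welch"),
                            recalc_method = "basis_floor",
                            include_unanalyzed = FALSE) {
  t_test <- match.arg(t_test)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  registry <- if (is.null(registry_path)) {
    default_registry()
  } else {
    load_locus_registry(registry_path)
  }
  ce <- parse_ce_table(ce_path)
  mps <- parse_mps_table(mps_path)
  totals <- if (!is.null(samples_path)) {
    readr::read_tsv(samples_path, col_types = readr::cols(
      sample_id = readr::col_character(),
      total_reads = readr::col_double()
    ))
  }
  res <- ystr_concordance(
    ce, mps,
    registry = registry, mps_sample_totals = totals,
    include_unanalyzed = include_unanalyzed,
    recalc_method = recalc_method, var_equal = t_test == "student"
  )
  files <- list(
    concordance = res$concordance,
    stutter_observations = res$stutters,
    stutter_summary = res$stutter_summary,
    stutter_tests = res$stutter_tests,
    balance = res$balance,
    balance_tests = res$balance_tests,
    census = res$census |>
      mutate(
        length_alleles = purrr::map_chr(
          .data$length_alleles, paste, collapse = ","
        ),
        variant_sequences = purrr::map_chr(
          .data$variant_sequences %||% list(), paste, collapse = ","
        )
      ),
    iso_alleles = res$iso_alleles
  )
  paths <- purrr::imap(files, function(tbl, nm) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(tbl, p)
    p
  })
  summary_path <- file.path(out_dir, "summary.txt")
  writeLines(utils::capture.output(print(res)), summary_path)
  manifest <- list(
    tool = "ystrconcord",
    version = as.character(packageVersion("ystrconcord")),
    command = "concord",
    inputs = list(
      ce = normalizePath(ce_path), mps = normalizePath(mps_path),
      registry = if (is.null(registry_path)) {
        "package default"
      } else {
        normalizePath(registry_path)
      },
      samples = if (is.null(samples_path)) {
        NULL
      } else {
        normalizePath(samples_path)
      }
    ),
    settings = list(
      t_test = t_test, recalc_method = recalc_method,
      include_unanalyzed = include_unanalyzed
    ),
    outputs = purrr::map(paths, normalizePath),
    counts = list(
      ce_peaks_parsed = nrow(ce),
      ce_rows_rejected = nrow(attr(ce, "rejects")),
      mps_records_parsed = nrow(mps),
      mps_rows_rejected = nrow(attr(mps, "rejects")),
      samples_gated_out = nrow(res$gated_out),
      ce_peak_calls = nrow(res$ce_calls),
      mps_sequence_calls = nrow(res$mps_calls),
      concordance_records = nrow(res$concordance),
      stutter_observations = nrow(res$stutters),
      balance_observations = nrow(res$balance)
    ),
    warnings = as.list(c(
      if (nrow(attr(ce, "rejects"))) "CE rows rejected" else NULL,
      if (nrow(attr(mps, "rejects"))) "MPS rows rejected" else NULL
    ))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(res)
}
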