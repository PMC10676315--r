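#' Compare CE and MPS calls per sample and locus
#'
#' Classifies every sample x locus as `concordant` (identical sorted
#' length-based allele sets), `apparent_discordant_grey_zone` (every
#' CE-only allele matches an MPS grey-zone candidate of the same length
#' and MPS called no extra alleles - the operator-review pattern),
#' `excluded_inconclusive` (the MPS locus carries the
#' `low_coverage_inc` flag), or `discordant`. Duplication (two alleles
#' at a single-copy locus) and deletion (no alleles on either platform)
#' patterns are concordant when both platforms agree, with a note.
#'
#' @param ce_calls Output of [call_ce_profiles()].
#' @param mps_calls Output of [call_mps_profiles()].
#' @param registry An `ystr_registry`.
#' @param loci Loci to compare; defaults to those analyzed on both
#'   platforms.
#' @param samples Samples to compare; defaults to every sample seen on
#'   either platform.
#' @return Concordance tibble: `sample_id`, `locus`, `ce_alleles`,
#'   `mps_alleles`, `status`, `notes`.
#' @export
compare_calls <- function(ce_calls, mps_calls, registry,
                          loci = analyzed_loci(registry, "both"),
                          samples = NULL) {
  samples <- samples %||%
    sort(union(unique(ce_calls$sample_id), unique(mps_calls$sample_id)))
  grid <- tidyr::crossing(sample_id = samples, locus = loci)
  ce_sets <- ce_calls |>
    filter(.data$status == "called") |>
    group_by(.data$sample_id, .data$locus) |>
    summarise(
      ce_alleles = list(sort_alleles(.data$allele)), .groups = "drop"
    )
  mps_called <- mps_calls |>
    filter(.data$status == "called") |>
    group_by(.data$sample_id, .data$locus) |>
    summarise(
      mps_alleles = list(sort_alleles(unique(.data$allele))),
      .groups = "drop"
    )
  mps_grey <- mps_calls |>
    filter(.data$status == "grey_zone") |>
    group_by(.data$sample_id, .data$locus) |>
    summarise(grey = list(unique(.data$allele)), .groups = "drop")
  mps_flags <- mps_calls |>
    group_by(.data$sample_id, .data$locus) |>
    summarise(
      inc = any(stringr::str_detect(.data$qc_flags, "low_coverage_inc")),
      has_records = TRUE, .groups = "drop"
    )
  grid |>
    left_join(ce_sets, by = c("sample_id", "locus")) |>
    left_join(mps_called, by = c("sample_id", "locus")) |>
    left_join(mps_grey, by = c("sample_id", "locus")) |>
    left_join(mps_flags, by = c("sample_id", "locus")) |>
    mutate(
      copy_number = purrr::map_chr(
        .data$locus, ~ registry$loci[[.x]]$copy_number
      ),
      ce = purrr::map(.data$ce_alleles, ~ .x %||% character()),
      mps = purrr::map(.data$mps_alleles, ~ .x %||% character()),
      grey = purrr::map(.data$grey, ~ .x %||% character()),
      inc = coalesce(.data$inc, FALSE),
      has_records = coalesce(.data$has_records, FALSE),
      equal_sets = purrr::map2_lgl(
        .data$ce, .data$mps,
        ~ length(.x) == length(.y) && setequal(.x, .y)
      ),
      ce_only = purrr::map2(.data$ce, .data$mps, setdiff),
      mps_only = purrr::map2(.data$mps, .data$ce, setdiff),
      grey_match = purrr::pmap_lgl(
        list(.data$ce_only, .data$mps_only, .data$grey),
        function(co, mo, g) length(mo) == 0 && length(co) > 0 && all(co %in% g)
      ),
      n_ce = lengths(.data$ce),
      status = case_when(
        .data$inc ~ "excluded_inconclusive",
        .data$equal_sets ~ "concordant",
        .data$grey_match ~ "apparent_discordant_grey_zone",
        TRUE ~ "discordant"
      ),
      notes = case_when(
        .data$status == "excluded_inconclusive" ~
          "no MPS sequence reached the interpretation threshold",
        .data$status == "concordant" & .data$copy_number == "single" &
          .data$n_ce >= 2 ~ "duplication confirmed",
        .data$status == "concordant" & .data$n_ce == 0 &
          !.data$has_records ~ "deletion confirmed",
        .data$status == "concordant" & .data$n_ce == 0 ~
          "no call on either platform",
        .data$status == "concordant" & .data$copy_number == "multi" &
          .data$n_ce >= 3 ~ "tri-allelic pattern",
        .data$status == "apparent_discordant_grey_zone" ~ paste0(
          "CE allele(s) ",
          purrr::map_chr(.data$ce_only, paste, collapse = ","),
          " present as MPS grey-zone candidate(s)"
        ),
        TRUE ~ ""
      ),
      ce_alleles = purrr::map_chr(.data$ce, paste, collapse = ","),
      mps_alleles = purrr::map_chr(.data$mps, paste, collapse = ",")
    ) |>
    select(
      "sample_id", "locus", "ce_alleles", "mps_alleles", "status", "notes"
    ) |>
    arrange(.data$sample_id, .data$locus)
}

sort_alleles <- function(x) {
  p <- parse_allele_label(x)
  x[order(p$repeats, p$partial_nt)]
}

#' Census of unique length- and sequence-based alleles
#'
#' Counts, per locus, the unique length-based alleles seen by either
#' platform, and the additional unique sequence-based alleles: called
#' MPS sequences whose string differs from the reference expansion of
#' their length allele (iso-alleles, variant homozygotes and variant
#' heterozygote sequences), deduplicated per locus. Sequence-based
#' additions are disjoint from the length-based entries by construction.
#'
#' @param ce_calls Output of [call_ce_profiles()] (may be zero rows).
#' @param mps_calls Output of [call_mps_profiles()] (may be zero rows or
#'   `NULL` for a CE-only census).
#' @return Tibble per locus: `locus`, `n_length_alleles`,
#'   `n_sequence_additional`, `length_alleles` and `variant_sequences`
#'   (list columns).
#' @export
census_alleles <- function(ce_calls, mps_calls = NULL) {
  ce_len <- ce_calls |>
    filter(.data$status == "called") |>
    distinct(.data$locus, .data$allele)
  if (!is.null(mps_calls) && nrow(mps_calls)) {
    mps_len <- mps_calls |>
      filter(.data$status == "called") |>
      distinct(.data$locus, .data$allele)
    var_seq <- mps_calls |>
      filter(.data$status == "called", .data$is_variant) |>
      distinct(.data$locus, .data$sequence)
  } else {
    mps_len <- tibble(locus = character(), allele = character())
    var_seq <- tibble(locus = character(), sequence = character())
  }
  lengths <- bind_rows(ce_len, mps_len) |> distinct()
  if (nrow(lengths) == 0 && nrow(var_seq) == 0) {
    return(tibble(
      locus = character(), n_length_alleles = integer(),
      n_sequence_additional = integer(),
      length_alleles = list(), variant_sequences = list()
    ))
  }
  len_tbl <- lengths |>
    group_by(.data$locus) |>
    summarise(
      n_length_alleles = n_distinct(.data$allele),
      length_alleles = list(sort_alleles(unique(.data$allele))),
      .groups = "drop"
    )
  var_tbl <- var_seq |>
    group_by(.data$locus) |>
    summarise(
      n_sequence_additional = n_distinct(.data$sequence),
      variant_sequences = list(sort(unique(.data$sequence))),
      .groups = "drop"
    )
  full_join(len_tbl, var_tbl, by = "locus") |>
    mutate(
      n_length_alleles = coalesce(.data$n_length_alleles, 0L),
      n_sequence_additional = coalesce(.data$n_sequence_additional, 0L)
    ) |>
    arrange(.data$locus)
}

#' Intra-locus balance of multicopy heterozygotes
#'
#' For every multicopy-locus heterozygote (two distinct typed alleles on
#' the platform in question) computes the percentage ratio of the minor
#' to the major signal - peak heights (RFU) for CE, read counts for MPS -
#' and flags observations below the platform threshold (65% CE, 60%
#' MPS by default). Tri-allelic genotypes are excluded from balance and
#' logged in the `"exclusions"` attribute.
#'
#' @param calls CE or MPS call tibble.
#' @param registry An `ystr_registry`.
#' @param platform `"CE"` or `"MPS"`.
#' @param thresholds Threshold configuration; defaults to the registry's.
#' @return Balance tibble: `sample_id`, `locus`, `platform`,
#'   `minor_signal`, `major_signal`, `ilb_pct`, `below_threshold`.
#'   Attribute `"exclusions"` lists excluded genotypes with a reason.
#' @export
compute_balance <- function(calls, registry, platform = c("CE", "MPS"),
                            thresholds = registry$thresholds) {
  platform <- match.arg(platform)
  check_known_loci(calls$locus, registry)
  multi <- names(purrr::keep(registry$loci, ~ .x$copy_number == "multi"))
  thr <- if (platform == "CE") {
    thresholds$ilb_threshold_ce
  } else {
    thresholds$ilb_threshold_mps
  }
  signal_col <- if (platform == "CE") "height_rfu" else "reads"
  called <- calls |>
    filter(.data$status == "called", .data$locus %in% multi)
  empty <- tibble(
    sample_id = character(), locus = character(), platform = character(),
    minor_signal = numeric(), major_signal = numeric(),
    ilb_pct = numeric(), below_threshold = logical()
  )
  exclusions <- tibble(
    sample_id = character(), locus = character(), reason = character()
  )
  if (nrow(called) == 0) {
    attr(empty, "exclusions") <- exclusions
    return(empty)
  }
  grouped <- called |>
    group_by(.data$sample_id, .data$locus) |>
    summarise(
      n_alleles = n(),
      minor_signal = min(.data[[signal_col]]),
      major_signal = max(.data[[signal_col]]),
      .groups = "drop"
    )
  exclusions <- grouped |>
    filter(.data$n_alleles >= 3) |>
    transmute(
      .data$sample_id, .data$locus,
      reason = "tri-allelic genotype excluded from balance"
    )
  out <- grouped |>
    filter(.data$n_alleles == 2) |>
    transmute(
      .data$sample_id, .data$locus,
      platform = platform,
      .data$minor_signal, .data$major_signal,
      ilb_pct = 100 * .data$minor_signal / .data$major_signal,
      below_threshold = .data$ilb_pct < thr
    )
  attr(out, "exclusions") <- exclusions
  out
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Classic pooled-variance two-sample t-test with
#' `df = nx + ny - 2`, a two-sided p-value and a confidence interval for
#' the mean difference, implemented directly so that degenerate inputs
#' (both groups constant) return a defined result (`t = 0, p = 1` when
#' the groups are identical) instead of an error. `var_equal = FALSE`
#' delegates to Welch's test via [stats::t.test()].
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @param var_equal Pooled-variance (Student) if `TRUE` (default),
#'   Welch otherwise.
#' @param conf_level Confidence level for the mean-difference interval.
#' @return One-row tibble: `estimate1`, `estimate2`, `estimate`
#'   (mean difference), `statistic`, `parameter` (df), `p.value`,
#'   `conf.low`, `conf.high`, `method`.
#' @examples
#' students_t(c(10, 12, 14), c(11, 13, 15))
#' @export
students_t <- function(x, y, var_equal = TRUE, conf_level = 0.95) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    abort("each group needs at least two observations")
  }
  if (!var_equal) {
    ht <- stats::t.test(x, y, var.equal = FALSE, conf.level = conf_level)
    return(tibble(
      estimate1 = mean(x), estimate2 = mean(y),
      estimate = mean(x) - mean(y),
      statistic = unname(ht$statistic), parameter = unname(ht$parameter),
      p.value = ht$p.value,
      conf.low = ht$conf.int[1], conf.high = ht$conf.int[2],
      method = "Welch two-sample t-test"
    ))
  }
  nx <- length(x)
  ny <- length(y)
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  diff <- mean(x) - mean(y)
  if (se == 0) {
    stat <- if (diff == 0) 0 else sign(diff) * Inf
    p <- if (diff == 0) 1 else 0
    ci <- c(diff, diff)
  } else {
    stat <- diff / se
    p <- 2 * pt(-abs(stat), df)
    ci <- diff + c(-1, 1) * qt(1 - (1 - conf_level) / 2, df) * se
  }
  tibble(
    estimate1 = mean(x), estimate2 = mean(y), estimate = diff,
    statistic = stat, parameter = df, p.value = p,
    conf.low = ci[1], conf.high = ci[2],
    method = "Student two-sample t-test (pooled variance)"
  )
}

#' Summarise stutter observations per locus and platform
#'
#' Excluded observations (multicopy overlaps) are omitted from all
#' statistics. Detection frequency is the fraction of eligible samples
#' (those with a called parent allele at the locus on that platform,
#' supplied via `parents`; all samples appearing in `observations`
#' otherwise) at which at least one stutter of that type was observed.
#' The count above the locus stutter filter uses the platform filter
#' from the registry.
#'
#' @param observations Stutter tibble from [collect_ce_stutters()] /
#'   [collect_mps_stutters()] (rows may be mixed platforms).
#' @param registry An `ystr_registry`.
#' @param parents Optional tibble `sample_id`, `locus`, `platform` of
#'   samples with a called parent allele, used as the detection-
#'   frequency denominator.
#' @param by_copy Split multicopy loci by parent copy (a/b), as the
#'   per-allele analysis does. Default `TRUE`.
#' @return Tibble per locus x platform x stutter type (x copy):
#'   `n`, `detection_freq_pct`, `min_pct`, `max_pct`, `mean_pct`,
#'   `sd_pct`, `n_above_filter`.
#' @export
summarize_stutters <- function(observations, registry, parents = NULL,
                               by_copy = TRUE) {
  obs <- observations |> filter(!.data$excluded)
  if (!by_copy) obs$parent_copy <- NA_character_
  filt <- purrr::map_dfr(registry$loci, ~ tibble(
    locus = .x$name,
    CE = .x$ce_minus_stutter_filter,
    MPS = .x$mps_stutter_filter
  )) |>
    tidyr::pivot_longer(c("CE", "MPS"),
      names_to = "platform", values_to = "filter_pct"
    )
  denom <- if (!is.null(parents)) {
    parents |>
      group_by(.data$locus, .data$platform) |>
      summarise(n_eligible = n_distinct(.data$sample_id), .groups = "drop")
  } else {
    observations |>
      group_by(.data$locus, .data$platform) |>
      summarise(n_eligible = n_distinct(.data$sample_id), .groups = "drop")
  }
  if (nrow(obs) == 0) {
    return(tibble(
      locus = character(), platform = character(), stutter_type = character(),
      parent_copy = character(), n = integer(), detection_freq_pct = numeric(),
      min_pct = numeric(), max_pct = numeric(), mean_pct = numeric(),
      sd_pct = numeric(), n_above_filter = integer()
    ))
  }
  obs |>
    left_join(filt, by = c("locus", "platform")) |>
    group_by(
      .data$locus, .data$platform, .data$stutter_type, .data$parent_copy
    ) |>
    summarise(
      n = n(),
      n_samples_detected = n_distinct(.data$sample_id),
      min_pct = min(.data$ratio_pct),
      max_pct = max(.data$ratio_pct),
      mean_pct = mean(.data$ratio_pct),
      sd_pct = sd(.data$ratio_pct),
      n_above_filter = sum(.data$ratio_pct > .data$filter_pct),
      .groups = "drop"
    ) |>
    left_join(denom, by = c("locus", "platform")) |>
    mutate(
      detection_freq_pct = 100 * .data$n_samples_detected /
        pmax(.data$n_eligible, 1L)
    ) |>
    select(
      "locus", "platform", "stutter_type", "parent_copy", "n",
      "detection_freq_pct", "min_pct", "max_pct", "mean_pct", "sd_pct",
      "n_above_filter"
    ) |>
    arrange(.data$locus, .data$platform, .data$stutter_type)
}

#' Per-locus CE-vs-MPS stutter ratio comparison
#'
#' Runs [students_t()] on the non-excluded minus-stutter percentage
#' ratios of each locus, CE against MPS, separately per detected copy
#' (a/b) at multicopy loci. Loci where either platform has fewer than
#' two observations are skipped.
#'
#' @inheritParams summarize_stutters
#' @param var_equal Passed to [students_t()].
#' @return Tibble per locus (x copy) with the [students_t()] columns.
#' @export
stutter_tests <- function(observations, var_equal = TRUE) {
  obs <- observations |>
    filter(!.data$excluded, .data$stutter_type == "minus_one_repeat")
  obs |>
    group_by(.data$locus, .data$parent_copy) |>
    group_modify(function(g, key) {
      x <- g$ratio_pct[g$platform == "CE"]
      y <- g$ratio_pct[g$platform == "MPS"]
      if (length(x) < 2 || length(y) < 2) {
        return(tibble())
      }
      students_t(x, y, var_equal = var_equal)
    }) |>
    ungroup()
}
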