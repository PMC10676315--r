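#' Parse a CE genotype peak table
#'
#' Reads a GeneMapper-style tab-delimited peak export with columns
#' `sample_id`, `locus`, `allele`, `size_bp`, `height_rfu`, `dye`.
#' Malformed rows (non-positive heights, unparseable allele labels) are
#' not silently dropped: they are collected into a rejects report
#' attached as the `"rejects"` attribute, with a message.
#'
#' @param source Path to a TSV file, or literal TSV text wrapped in
#'   [I()] (anything [readr::read_tsv()] accepts).
#' @return Tibble of peaks; attribute `"rejects"` holds the rejected rows
#'   with a `reject_reason` column.
#' @export
parse_ce_table <- function(source) {
  tbl <- readr::read_tsv(source, col_types = readr::cols(
    sample_id = readr::col_character(),
    locus = readr::col_character(),
    allele = readr::col_character(),
    size_bp = readr::col_double(),
    height_rfu = readr::col_double(),
    dye = readr::col_character()
  ))
  required <- c("sample_id", "locus", "allele", "size_bp", "height_rfu", "dye")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    abort(paste0(
      "CE table is missing required columns: ",
      paste(missing, collapse = ", ")
    ))
  }
  parsed <- parse_allele_label(tbl$allele)
  bad_height <- is.na(tbl$height_rfu) | tbl$height_rfu <= 0
  bad_allele <- is.na(parsed$repeats)
  bad <- bad_height | bad_allele
  rejects <- tbl[bad, , drop = FALSE] |>
    mutate(reject_reason = case_when(
      bad_height[bad] ~ "non-positive height",
      TRUE ~ "unparseable allele label"
    ))
  if (nrow(rejects)) {
    warn(paste0(nrow(rejects), " CE row(s) rejected; see attr(x, 'rejects')"))
  }
  out <- tbl[!bad, , drop = FALSE]
  attr(out, "rejects") <- rejects
  out
}

#' Call a CE locus genotype
#'
#' Applies the CE calling regime to the peaks of one sample at one locus:
#' peaks below the peak amplitude threshold (PAT) are removed first; a
#' surviving peak one repeat below (or above, or two nucleotides below) a
#' taller surviving peak is labelled stutter when its height ratio does
#' not exceed the locus stutter filter; a lone surviving peak must reach
#' the homozygous minimum to be called, while two or more surviving
#' candidates must each reach the heterozygous minimum.
#'
#' @param peaks Tibble of peaks for a single sample x locus (columns
#'   `allele`, `height_rfu`, plus identifiers).
#' @param locus_def Locus definition from the registry.
#' @param thresholds A [threshold_config()].
#' @return The peaks tibble with `status` (`"called"`/`"filtered"`),
#'   `filter_reason` (`below_pat`, `stutter_filtered`, `below_het`,
#'   `below_hom`, or `NA`), and a call-level `zygosity` column
#'   (`no_call`, `single_peak`, `heterozygous`, `multi_allelic`).
#' @export
call_ce_locus <- function(peaks, locus_def, thresholds) {
  stopifnot(inherits(locus_def, "locus_definition"))
  unit <- locus_def$repeat_unit_length
  parsed <- parse_allele_label(peaks$allele)
  if (anyNA(parsed$repeats)) {
    abort("unparseable allele labels; run parse_ce_table() first")
  }
  n <- nrow(peaks)
  status <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  nt <- allele_nt(parsed$repeats, parsed$partial_nt, unit)

  reason[peaks$height_rfu < thresholds$pat_rfu] <- "below_pat"

  # stutter filtering relative to taller surviving non-stutter peaks
  surv <- which(is.na(reason))
  ord <- surv[order(-peaks$height_rfu[surv])]
  allele_idx <- integer()
  filters <- c(
    minus = locus_def$ce_minus_stutter_filter,
    plus = locus_def$ce_plus_stutter_filter,
    minus2 = locus_def$ce_minus2_stutter_filter
  )
  deltas <- c(minus = -unit, plus = unit, minus2 = -2L)
  for (i in ord) {
    is_stutter <- FALSE
    for (j in allele_idx) {
      for (tp in names(filters)) {
        if (is.na(filters[[tp]])) next
        if (nt[i] == nt[j] + deltas[[tp]] &&
          100 * peaks$height_rfu[i] / peaks$height_rfu[j] <= filters[[tp]]) {
          is_stutter <- TRUE
          break
        }
      }
      if (is_stutter) break
    }
    if (is_stutter) {
      reason[i] <- "stutter_filtered"
    } else {
      allele_idx <- c(allele_idx, i)
    }
  }

  cand <- which(is.na(reason))
  if (length(cand) == 1) {
    if (peaks$height_rfu[cand] >= thresholds$ce_hom_rfu) {
      status[cand] <- "called"
    } else {
      reason[cand] <- "below_hom"
    }
  } else if (length(cand) >= 2) {
    low <- cand[peaks$height_rfu[cand] < thresholds$ce_het_rfu]
    reason[low] <- "below_het"
    status[setdiff(cand, low)] <- "called"
  }
  status[is.na(status)] <- "filtered"
  n_called <- sum(status == "called")
  zyg <- case_when(
    n_called == 0 ~ "no_call",
    n_called == 1 ~ "single_peak",
    n_called == 2 ~ "heterozygous",
    TRUE ~ "multi_allelic"
  )
  peaks |>
    mutate(
      repeats = parsed$repeats, partial_nt = parsed$partial_nt,
      status = status, filter_reason = reason, zygosity = zyg
    )
}

#' Call CE genotypes for a whole peak table
#'
#' Maps [call_ce_locus()] over every sample x locus group of a parsed
#' peak table. Loci absent from the registry are a hard error listing the
#' offenders.
#'
#' @param peaks Tibble from [parse_ce_table()] (or the simulator).
#' @param registry An `ystr_registry`.
#' @param thresholds Threshold configuration; defaults to the registry's.
#' @return Per-peak call tibble (see [call_ce_locus()]).
#' @export
call_ce_profiles <- function(peaks, registry,
                             thresholds = registry$thresholds) {
  check_known_loci(peaks$locus, registry)
  peaks |>
    group_by(.data$sample_id, .data$locus) |>
    group_modify(~ call_ce_locus(
      .x, registry$loci[[.y$locus]], thresholds
    )) |>
    ungroup()
}

#' Collect CE stutter observations
#'
#' Records one observation per (called parent allele, stutter-position
#' peak) pair with the percentage ratio of the stutter peak height to the
#' parent peak height. Observations are collected on every surviving
#' stutter-position peak regardless of the stutter filter - the filter
#' affects allele calling only, so above-filter stutters remain
#' observable. A peak that is simultaneously one repeat below one parent
#' and one repeat above another is assigned the minus interpretation
#' (minus stutter dominates) and flagged ambiguous. At multicopy loci
#' with called alleles exactly one repeat apart, the larger allele's
#' minus stutter (which overlaps the smaller allele's peak) and the
#' smaller allele's plus stutter are marked excluded.
#'
#' @param calls Output of [call_ce_profiles()].
#' @param registry An `ystr_registry`.
#' @return Stutter-observation tibble: `sample_id`, `locus`, `platform`,
#'   `parent_allele`, `parent_copy`, `stutter_type`, `stutter_allele`,
#'   `signal`, `parent_signal`, `ratio_pct`, `excluded`,
#'   `exclusion_reason`, `note`.
#' @export
collect_ce_stutters <- function(calls, registry) {
  check_known_loci(calls$locus, registry)
  empty <- tibble(
    sample_id = character(), locus = character(), platform = character(),
    parent_allele = character(), parent_copy = character(),
    stutter_type = character(), stutter_allele = character(),
    signal = numeric(), parent_signal = numeric(), ratio_pct = numeric(),
    excluded = logical(), exclusion_reason = character(), note = character()
  )
  locus_meta <- purrr::map_dfr(registry$loci, ~ tibble(
    locus = .x$name, unit = .x$repeat_unit_length,
    multicopy = .x$copy_number == "multi"
  ))
  parents <- calls |>
    filter(.data$status == "called") |>
    left_join(locus_meta, by = "locus") |>
    group_by(.data$sample_id, .data$locus) |>
    arrange(.data$repeats, .data$partial_nt, .by_group = TRUE) |>
    mutate(
      parent_copy = if_else(.data$multicopy, letters[row_number()],
        NA_character_
      ),
      nt = allele_nt(.data$repeats, .data$partial_nt, .data$unit),
      # a called sibling exactly one repeat below / above this allele?
      adj_smaller = (.data$nt - .data$unit) %in% .data$nt,
      adj_larger = (.data$nt + .data$unit) %in% .data$nt
    ) |>
    ungroup()
  if (nrow(parents) == 0) {
    return(empty)
  }
  surviving <- calls |>
    filter(is.na(.data$filter_reason) | .data$filter_reason != "below_pat") |>
    select("sample_id", "locus",
      stutter_allele = "allele", signal = "height_rfu"
    )
  cand <- parents |>
    tidyr::crossing(
      stutter_type = c("minus_one_repeat", "plus_one_repeat", "minus_2nt")
    ) |>
    mutate(
      delta = case_when(
        .data$stutter_type == "minus_one_repeat" ~ -.data$unit,
        .data$stutter_type == "plus_one_repeat" ~ .data$unit,
        TRUE ~ -2L
      ),
      stutter_allele = shift_allele_label(
        .data$repeats, .data$partial_nt, .data$unit, .data$delta
      )
    ) |>
    filter(!is.na(.data$stutter_allele))
  obs <- cand |>
    inner_join(surviving, by = c("sample_id", "locus", "stutter_allele")) |>
    transmute(
      .data$sample_id, .data$locus,
      platform = "CE",
      parent_allele = .data$allele, .data$parent_copy,
      .data$stutter_type, .data$stutter_allele,
      .data$signal, parent_signal = .data$height_rfu,
      ratio_pct = 100 * .data$signal / .data$height_rfu,
      excluded = .data$multicopy &
        ((.data$stutter_type == "minus_one_repeat" & .data$adj_smaller) |
          (.data$stutter_type == "plus_one_repeat" & .data$adj_larger)),
      exclusion_reason = case_when(
        .data$multicopy & .data$stutter_type == "minus_one_repeat" &
          .data$adj_smaller ~ "overlaps_smaller_allele",
        .data$multicopy & .data$stutter_type == "plus_one_repeat" &
          .data$adj_larger ~ "overlaps_larger_allele",
        TRUE ~ "none"
      ),
      note = NA_character_
    )
  if (nrow(obs) == 0) {
    return(empty)
  }
  # tie rule: a peak claimed as minus stutter of one parent and plus
  # stutter of another keeps the minus interpretation, flagged ambiguous
  obs |>
    group_by(.data$sample_id, .data$locus, .data$stutter_allele) |>
    mutate(tie = any(.data$stutter_type == "minus_one_repeat") &
      any(.data$stutter_type == "plus_one_repeat")) |>
    ungroup() |>
    filter(!(.data$tie & .data$stutter_type == "plus_one_repeat")) |>
    mutate(note = if_else(.data$tie, "ambiguous", .data$note)) |>
    select(-"tie") |>
    arrange(.data$sample_id, .data$locus, .data$parent_allele)
}
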