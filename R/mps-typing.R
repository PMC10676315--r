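#' Parse an MPS sequence-read table
#'
#' Reads a UAS-style tab-delimited per-locus read table with columns
#' `sample_id`, `locus`, `sequence`, `reads`, `typed_flag`. Rows with
#' non-positive read counts or sequences outside A/C/G/T go to a rejects
#' report (attribute `"rejects"`), never silently dropped.
#'
#' @inheritParams parse_ce_table
#' @return Tibble of records with a `"rejects"` attribute.
#' @export
parse_mps_table <- function(source) {
  tbl <- readr::read_tsv(source, col_types = readr::cols(
    sample_id = readr::col_character(),
    locus = readr::col_character(),
    sequence = readr::col_character(),
    reads = readr::col_double(),
    typed_flag = readr::col_character()
  ))
  required <- c("sample_id", "locus", "sequence", "reads", "typed_flag")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    abort(paste0(
      "MPS table is missing required columns: ",
      paste(missing, collapse = ", ")
    ))
  }
  bad_reads <- is.na(tbl$reads) | tbl$reads < 1
  bad_seq <- is.na(tbl$sequence) | tbl$sequence == "" |
    stringr::str_detect(tbl$sequence, "[^ACGT]")
  bad <- bad_reads | bad_seq
  rejects <- tbl[bad, , drop = FALSE] |>
    mutate(reject_reason = case_when(
      bad_reads[bad] ~ "reads < 1",
      TRUE ~ "sequence not over A/C/G/T"
    ))
  if (nrow(rejects)) {
    warn(paste0(nrow(rejects), " MPS row(s) rejected; see attr(x, 'rejects')"))
  }
  out <- tbl[!bad, , drop = FALSE]
  attr(out, "rejects") <- rejects
  out
}

#' Apply the total-sample read gate
#'
#' MPS runs are kept only when the total sample read count reaches the
#' gate (default 85,000 reads). Samples failing the gate are excluded
#' from all downstream tallies.
#'
#' @param samples Tibble with columns `sample_id` and `total_reads`.
#' @param thresholds A [threshold_config()].
#' @return The input with a logical `pass` column.
#' @export
gate_samples <- function(samples, thresholds = threshold_config()) {
  samples |>
    mutate(pass = .data$total_reads >= thresholds$mps_sample_read_gate)
}

#' Recalculate MPS analytical and interpretation thresholds
#'
#' Converts the locus AT/IT percentages into read counts. Under the
#' default `"basis_floor"` rule the percentage is taken of
#' `max(locus_reads, basis_reads)` and rounded up, which reproduces the
#' documented floors (1.5% and 4.5% of a 650-read basis give 10 and 30
#' reads: 9.75 and 29.25 rounded up). The alternative `"hard_floor"`
#' rule takes the percentage of the actual locus reads and clamps the
#' results at the 650-basis floors; both readings satisfy the published
#' description and are selectable here.
#'
#' @param locus_reads Numeric vector of total locus read counts.
#' @param at_pct,it_pct Analytical / interpretation threshold
#'   percentages (defaults 1.5 and 4.5).
#' @param basis_reads Minimum recalculation basis (default 650 reads).
#' @param method `"basis_floor"` (default) or `"hard_floor"`.
#' @return Tibble with columns `locus_reads`, `at_reads`, `it_reads`.
#' @examples
#' recalc_thresholds(650) # 10 and 30 reads
#' recalc_thresholds(2000) # 30 and 90 reads
#' @export
recalc_thresholds <- function(locus_reads, at_pct = 1.5, it_pct = 4.5,
                              basis_reads = 650,
                              method = c("basis_floor", "hard_floor")) {
  method <- match.arg(method)
  stopifnot(all(locus_reads >= 0), at_pct > 0, at_pct < it_pct)
  if (method == "basis_floor") {
    basis <- pmax(locus_reads, basis_reads)
    at <- ceiling(at_pct / 100 * basis)
    it <- ceiling(it_pct / 100 * basis)
  } else {
    at <- pmax(ceiling(at_pct / 100 * locus_reads),
      ceiling(at_pct / 100 * basis_reads))
    it <- pmax(ceiling(it_pct / 100 * locus_reads),
      ceiling(it_pct / 100 * basis_reads))
  }
  tibble(locus_reads = locus_reads, at_reads = at, it_reads = it)
}

#' Call an MPS locus genotype
#'
#' Applies the MPS threshold machinery to the sequence records of one
#' sample at one locus. The locus AT/IT percentages are converted to
#' read counts with [recalc_thresholds()]; sequences below the
#' analytical threshold are discarded; sequences between the thresholds
#' become grey-zone candidates, surfaced for operator review but never
#' promoted to calls automatically; sequences at or above the
#' interpretation threshold are called unless they are sequence-exact
#' stutters (one expandable repeat removed or added) of an
#' already-called parent within the locus stutter filter. A locus where
#' no sequence reaches the interpretation threshold is flagged
#' `low_coverage_inc` (inconclusive).
#'
#' @param records Tibble of records for one sample x locus (`sequence`,
#'   `reads`, `typed_flag`).
#' @param locus_def Locus definition.
#' @param thresholds A [threshold_config()].
#' @param recalc_method Passed to [recalc_thresholds()].
#' @return Per-sequence tibble with bracket notation, allele
#'   designation, `is_variant`, `status` (`called`, `grey_zone`,
#'   `stutter`, `discarded`), `stutter_of`, `copy` (a/b/c for called
#'   alleles at multicopy loci), `locus_reads`, `at_reads`, `it_reads`
#'   and a semicolon-joined `qc_flags` column.
#' @export
call_mps_locus <- function(records, locus_def, thresholds,
                           recalc_method = "basis_floor",
                           bracket_lookup = NULL) {
  stopifnot(inherits(locus_def, "locus_definition"))
  locus_reads <- sum(records$reads)
  thr <- recalc_thresholds(
    locus_reads, locus_def$at_pct, locus_def$it_pct,
    thresholds$mps_recalc_basis_reads, recalc_method
  )
  br <- if (is.null(bracket_lookup)) {
    purrr::map_dfr(records$sequence, bracket_sequence, locus_def)
  } else {
    tibble(sequence = records$sequence) |>
      left_join(bracket_lookup, by = "sequence")
  }
  out <- records |>
    mutate(
      bracket = br$bracket, allele = br$allele, repeats = br$repeats,
      partial_nt = br$partial_nt, is_variant = br$is_variant,
      locus_reads = locus_reads,
      at_reads = thr$at_reads, it_reads = thr$it_reads,
      status = NA_character_, stutter_of = NA_character_,
      copy = NA_character_
    ) |>
    arrange(
      desc(.data$reads), desc(.data$repeats), desc(.data$partial_nt),
      .data$sequence
    )
  called_idx <- integer()
  classify <- function(i) {
    for (j in called_idx) {
      rel <- stutter_relation(out$sequence[j], out$sequence[i], locus_def)
      if (!is.na(rel) &&
        100 * out$reads[i] / out$reads[j] <= locus_def$mps_stutter_filter) {
        return(list(status = "stutter", parent = out$allele[j]))
      }
    }
    NULL
  }
  for (i in seq_len(nrow(out))) {
    if (out$reads[i] >= out$it_reads[i]) {
      st <- classify(i)
      if (is.null(st)) {
        out$status[i] <- "called"
        called_idx <- c(called_idx, i)
      } else {
        out$status[i] <- "stutter"
        out$stutter_of[i] <- st$parent
      }
    } else if (out$reads[i] > out$at_reads[i]) {
      st <- classify(i)
      if (is.null(st)) {
        out$status[i] <- "grey_zone"
      } else {
        out$status[i] <- "stutter"
        out$stutter_of[i] <- st$parent
      }
    } else {
      out$status[i] <- "discarded"
    }
  }
  flags <- character()
  if (any(out$status == "grey_zone")) flags <- c(flags, "grey_zone")
  if (!any(out$status == "called") && nrow(out) > 0) {
    flags <- c(flags, "low_coverage_inc")
  }
  called <- which(out$status == "called")
  if (length(called) && locus_def$copy_number == "multi") {
    ord <- called[order(out$repeats[called], out$partial_nt[called],
      out$sequence[called])]
    out$copy[ord] <- letters[seq_along(ord)]
  }
  out$qc_flags <- paste(flags, collapse = ";")
  out
}

#' Call MPS genotypes for a whole read table
#'
#' Maps [call_mps_locus()] over every sample x locus group. Loci absent
#' from the registry are a hard error.
#'
#' @param records Tibble from [parse_mps_table()] (or the simulator).
#' @param registry An `ystr_registry`.
#' @param thresholds Threshold configuration; defaults to the registry's.
#' @param recalc_method Passed to [recalc_thresholds()].
#' @return Per-sequence call tibble (see [call_mps_locus()]).
#' @export
call_mps_profiles <- function(records, registry,
                              thresholds = registry$thresholds,
                              recalc_method = "basis_floor") {
  check_known_loci(records$locus, registry)
  # bracket each distinct (locus, sequence) once; sequences recur across
  # samples, so this dominates the cost otherwise
  uniq <- distinct(records, .data$locus, .data$sequence)
  brackets <- purrr::map2_dfr(
    uniq$sequence, uniq$locus,
    ~ bracket_sequence(.x, registry$loci[[.y]])
  ) |>
    select(
      "locus", "sequence", "bracket", "allele", "repeats", "partial_nt",
      "is_variant"
    )
  lookup <- split(
    brackets |> select(-"locus"),
    brackets$locus
  )
  records |>
    group_by(.data$sample_id, .data$locus) |>
    group_modify(~ call_mps_locus(
      .x, registry$loci[[.y$locus]], thresholds, recalc_method,
      bracket_lookup = lookup[[.y$locus]]
    )) |>
    ungroup()
}

#' Detect iso-alleles and variant homozygotes at multicopy loci
#'
#' Iso-alleles are called alleles of identical length but different
#' repeat-region sequence, a homozygosity pattern only sequencing can
#' resolve. A single called sequence that differs from the reference
#' expansion of its length allele at a multicopy locus is the
#' variant-homozygote category (both copies share the mutated
#' sequence), which manual review rather than the typing software
#' identifies.
#'
#' @param calls Output of [call_mps_profiles()].
#' @param registry An `ystr_registry`.
#' @return Tibble `sample_id`, `locus`, `category` (`"iso_allele_pair"`
#'   or `"variant_homozygote"`), `allele`, `sequences` (slash-joined).
#' @export
detect_iso_alleles <- function(calls, registry) {
  check_known_loci(calls$locus, registry)
  multi <- names(purrr::keep(registry$loci, ~ .x$copy_number == "multi"))
  called <- calls |>
    filter(.data$status == "called", .data$locus %in% multi)
  if (nrow(called) == 0) {
    return(tibble(
      sample_id = character(), locus = character(), category = character(),
      allele = character(), sequences = character()
    ))
  }
  iso <- called |>
    group_by(.data$sample_id, .data$locus, .data$allele) |>
    filter(n() >= 2, n_distinct(.data$sequence) >= 2) |>
    summarise(
      category = "iso_allele_pair",
      sequences = paste(sort(unique(.data$sequence)), collapse = "/"),
      .groups = "drop"
    )
  varhom <- called |>
    group_by(.data$sample_id, .data$locus) |>
    filter(n() == 1, .data$is_variant) |>
    summarise(
      category = "variant_homozygote",
      allele = .data$allele[1], sequences = .data$sequence[1],
      .groups = "drop"
    )
  bind_rows(iso, varhom) |>
    select("sample_id", "locus", "category", "allele", "sequences") |>
    arrange(.data$sample_id, .data$locus)
}

#' Collect MPS stutter observations
#'
#' An untyped (non-called) sequence is a stutter of a called parent iff
#' it equals the parent's sequence with exactly one expandable-block
#' repeat removed (n-1) or added (n+1) - string equality after the
#' repeat edit is required, so a one-repeat-shorter sequence of a
#' different variant string is not the parent's stutter. The ratio is
#' the stutter reads over the parent reads, collected on records above
#' the analytical threshold regardless of the stutter filter. Multicopy
#' one-repeat-apart overlap exclusions are applied as in
#' [collect_ce_stutters()]; when adjacent alleles share a sequence type
#' the larger allele's n-1 stutter string coincides with the smaller
#' allele's own record, and that overlapped signal is recorded as an
#' excluded observation.
#'
#' @param calls Output of [call_mps_profiles()].
#' @param registry An `ystr_registry`.
#' @return Stutter-observation tibble in the same schema as
#'   [collect_ce_stutters()].
#' @export
collect_mps_stutters <- function(calls, registry) {
  empty <- tibble(
    sample_id = character(), locus = character(), platform = character(),
    parent_allele = character(), parent_copy = character(),
    stutter_type = character(), stutter_allele = character(),
    signal = numeric(), parent_signal = numeric(), ratio_pct = numeric(),
    excluded = logical(), exclusion_reason = character(), note = character()
  )
  if (nrow(calls) == 0) {
    return(empty)
  }
  check_known_loci(calls$locus, registry)
  locus_meta <- purrr::map_dfr(registry$loci, ~ tibble(
    locus = .x$name, unit = .x$repeat_unit_length,
    multicopy = .x$copy_number == "multi"
  ))
  parents <- calls |>
    filter(.data$status == "called") |>
    left_join(locus_meta, by = "locus") |>
    group_by(.data$sample_id, .data$locus) |>
    mutate(
      nt = allele_nt(.data$repeats, .data$partial_nt, .data$unit),
      adj_smaller = (.data$nt - .data$unit) %in% .data$nt,
      adj_larger = (.data$nt + .data$unit) %in% .data$nt
    ) |>
    ungroup()
  if (nrow(parents) == 0) {
    return(empty)
  }
  # stutters are detectable above the analytical threshold only
  children <- calls |>
    filter(.data$status %in% c("stutter", "grey_zone")) |>
    select("sample_id", "locus",
      child_sequence = "sequence", child_allele = "allele",
      child_reads = "reads"
    )
  pairs <- parents |>
    inner_join(children,
      by = c("sample_id", "locus"), relationship = "many-to-many"
    )
  rel <- if (nrow(pairs)) {
    purrr::pmap_chr(
      list(pairs$sequence, pairs$child_sequence, pairs$locus),
      function(p, ch, lc) stutter_relation(p, ch, registry$loci[[lc]])
    )
  } else {
    character()
  }
  obs <- pairs |>
    mutate(stutter_type = rel) |>
    filter(!is.na(.data$stutter_type)) |>
    transmute(
      .data$sample_id, .data$locus,
      platform = "MPS",
      parent_allele = .data$allele, parent_copy = .data$copy,
      .data$stutter_type, stutter_allele = .data$child_allele,
      signal = .data$child_reads, parent_signal = .data$reads,
      ratio_pct = 100 * .data$child_reads / .data$reads,
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
  # overlapped signal at adjacent same-sequence-type called alleles: the
  # larger allele's n-1 stutter string is the smaller allele's own record
  # (and vice versa in the plus direction); record both as excluded
  ap <- parents |>
    filter(.data$multicopy, .data$adj_smaller | .data$adj_larger)
  overlap_obs <- empty
  if (nrow(ap)) {
    pp <- ap |>
      inner_join(
        ap |> select("sample_id", "locus",
          sib_sequence = "sequence", sib_allele = "allele",
          sib_reads = "reads", sib_copy = "copy", sib_nt = "nt"
        ),
        by = c("sample_id", "locus"), relationship = "many-to-many"
      ) |>
      filter(.data$sib_nt == .data$nt - .data$unit)
    if (nrow(pp)) {
      srel <- purrr::pmap_chr(
        list(pp$sequence, pp$sib_sequence, pp$locus),
        function(p, ch, lc) stutter_relation(p, ch, registry$loci[[lc]])
      )
      pp <- pp[!is.na(srel) & srel == "minus_one_repeat", ]
      if (nrow(pp)) {
        overlap_obs <- bind_rows(
          pp |> transmute(
            .data$sample_id, .data$locus, platform = "MPS",
            parent_allele = .data$allele, parent_copy = .data$copy,
            stutter_type = "minus_one_repeat",
            stutter_allele = .data$sib_allele,
            signal = .data$sib_reads, parent_signal = .data$reads,
            ratio_pct = 100 * .data$sib_reads / .data$reads,
            excluded = TRUE, exclusion_reason = "overlaps_smaller_allele",
            note = "overlaps called allele"
          ),
          pp |> transmute(
            .data$sample_id, .data$locus, platform = "MPS",
            parent_allele = .data$sib_allele, parent_copy = .data$sib_copy,
            stutter_type = "plus_one_repeat",
            stutter_allele = .data$allele,
            signal = .data$reads, parent_signal = .data$sib_reads,
            ratio_pct = 100 * .data$reads / .data$sib_reads,
            excluded = TRUE, exclusion_reason = "overlaps_larger_allele",
            note = "overlaps called allele"
          )
        )
      }
    }
  }
  obs <- bind_rows(obs, overlap_obs)
  if (nrow(obs) == 0) {
    return(empty)
  }
  # tie rule: a record claimed as minus of one parent and plus of another
  # keeps only the minus interpretation
  obs |>
    group_by(.data$sample_id, .data$locus, .data$stutter_allele) |>
    mutate(tie = any(.data$stutter_type == "minus_one_repeat") &
      any(.data$stutter_type == "plus_one_repeat") &
      !all(.data$excluded)) |>
    ungroup() |>
    filter(!(.data$tie & .data$stutter_type == "plus_one_repeat" &
      !.data$excluded)) |>
    mutate(note = if_else(.data$tie & is.na(.data$note), "ambiguous",
      .data$note
    )) |>
    select(-"tie") |>
    arrange(.data$sample_id, .data$locus, .data$parent_allele)
}
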