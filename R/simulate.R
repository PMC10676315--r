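#' Configure the paired-profile simulator
#'
#' Builds the parameter set for generating paired CE peak tables and MPS
#' sequence-read tables for single-source male Y-STR profiles. Defaults
#' emulate a 125-sample concordance study: per-locus depth of coverage is
#' negative-binomial around a panel mean of 789 reads (extremes at
#' Y-GATA-H4 and DYS438), CE parent peaks are lognormal, stutter ratios
#' are truncated-normal with means that scale inversely with repeat-unit
#' length, multicopy heterozygote balance is Beta-distributed, and
#' isometric sequence variants occur at eight variant-prone loci. Scenario
#' flags inject the study's special cases: a grey-zone allele dropout at a
#' multicopy locus, a tri-allelic pattern, a duplication, a deletion, and
#' a chronically low-coverage locus.
#'
#' @param n_samples Number of simulated donors (default 125).
#' @param seed Integer RNG seed; every generator function derives its
#'   stream from it, so identical `(config, seed)` give byte-identical
#'   tables.
#' @param registry Locus registry ([default_registry()] if omitted).
#' @param locus_params Optional tibble of per-locus overrides; any subset
#'   of the columns of the default parameter table, keyed by `locus`.
#' @param ilb_beta_shape1,ilb_beta_shape2 Beta shape parameters for the
#'   multicopy heterozygote balance draw applied to the higher-molecular-
#'   weight copy (defaults 9 and 1.5, mean balance ~86%).
#' @param noise_peak_rate Probability of one sub-PAT noise peak per CE
#'   sample x locus (default 0.05).
#' @param background_reads_mean,background_reads_sd Normal draw added to
#'   the per-sample Y-STR reads to form the reported total sample read
#'   count, emulating the non-Y content of the sequencing panel
#'   (defaults 78000 and 2000, giving totals near 93,000).
#' @param low_coverage_mean_doc Mean depth forced on the low-coverage
#'   scenario locus (default 25 reads, below the 30-read IT floor).
#' @param inject_grey_zone_dropout,inject_triallelic,inject_duplication,inject_deletion,inject_low_coverage_locus
#'   Scenario switches (all `TRUE` by default, matching the events the
#'   study conditions contain; switch all off for a clean run).
#' @return A list of class `ystr_sim_config`.
#' @export
simulation_config <- function(n_samples = 125, seed = 20230,
                              registry = default_registry(),
                              locus_params = NULL,
                              ilb_beta_shape1 = 9, ilb_beta_shape2 = 1.5,
                              noise_peak_rate = 0.05,
                              background_reads_mean = 78000,
                              background_reads_sd = 2000,
                              low_coverage_mean_doc = 25,
                              inject_grey_zone_dropout = TRUE,
                              inject_triallelic = TRUE,
                              inject_duplication = TRUE,
                              inject_deletion = TRUE,
                              inject_low_coverage_locus = TRUE) {
  params <- default_locus_params(registry)
  if (!is.null(locus_params)) {
    locus_params <- as_tibble(locus_params)
    stopifnot("locus" %in% names(locus_params))
    params <- rows_update(params, locus_params, by = "locus")
  }
  structure(list(
    n_samples = as.integer(n_samples),
    seed = as.integer(seed),
    registry = registry,
    locus_params = params,
    ilb_beta_shape1 = ilb_beta_shape1,
    ilb_beta_shape2 = ilb_beta_shape2,
    noise_peak_rate = noise_peak_rate,
    background_reads_mean = background_reads_mean,
    background_reads_sd = background_reads_sd,
    low_coverage_mean_doc = low_coverage_mean_doc,
    scenarios = list(
      grey_zone = inject_grey_zone_dropout,
      triallelic = inject_triallelic,
      duplication = inject_duplication,
      deletion = inject_deletion,
      low_coverage = inject_low_coverage_locus
    ),
    # designated scenario anchors (sample index, locus, genotype)
    grey_zone_locus = "DYS385 a/b",
    grey_zone_alleles = c(14L, 19L),
    grey_zone_parent_reads = 280,
    grey_zone_dropout_reads = 19,
    triallelic_locus = "DYF387S1",
    triallelic_alleles = c(37L, 38L, 39L),
    duplication_locus = "DYS448",
    deletion_locus = "DYS570",
    low_coverage_locus = "DYS392"
  ), class = "ystr_sim_config")
}

# per-locus simulation defaults: depth, signal and stutter distributions.
# Stutter means scale with repeat-unit length (tri > tetra > penta > hexa),
# mirroring the slippage-rate trend across unit sizes.
default_locus_params <- function(registry) {
  doc <- c(
    "Y-GATA-H4" = 213, "DYS438" = 3091, "DYS389II" = 450,
    "DYS385 a/b" = 900, "DYF387S1" = 850, "DYS481" = 1200,
    "DYS448" = 500, "DYS392" = 380, "DYS19" = 600
  )
  plus_loci <- c("DYS389I", "DYS390", "DYS437", "DYS439", "DYS481", "DYS576")
  variant_loci <- c(
    "DYF387S1", "DYS389II", "DYS448", "DYS635", "DYS570",
    "DYS481", "DYS19", "DYS438"
  )
  purrr::map_dfr(registry$loci, function(ld) {
    unit <- ld$repeat_unit_length
    tibble(
      locus = ld$name,
      mean_doc = unname(doc[ld$name]) %|na|% 789,
      doc_dispersion = 8,
      ce_mean_rfu = 2000,
      ce_rfu_cv = 0.35,
      minus_stutter_mean_pct = switch(as.character(unit),
        "3" = if (ld$name == "DYS392") 10 else 14, "4" = 9, "5" = 4, "6" = 3
      ),
      minus_stutter_sd_pct = switch(as.character(unit),
        "3" = 2.5, "4" = 1.3, "5" = 1, "6" = 1
      ),
      plus_stutter_mean_pct = if (ld$name %in% plus_loci) 1.5 else 0,
      plus_stutter_sd_pct = 0.4,
      minus2_stutter_mean_pct = 0,
      seq_variant_rate = if (ld$name %in% variant_loci) 0.25 else 0
    )
  })
}

`%|na|%` <- function(x, y) if (is.null(x) || is.na(x)) y else x

# single-base substitution at position 2 of a motif (A>G, C>T, G>A, T>C):
# yields an alternate unit of identical length, the isometric-variant
# building block
mutate_motif <- function(motif) {
  map <- c(A = "G", C = "T", G = "A", T = "C")
  paste0(
    substr(motif, 1, 1), map[[substr(motif, 2, 2)]],
    substr(motif, 3, nchar(motif))
  )
}

#' Simulate ground-truth Y-STR profiles
#'
#' Draws true genotypes for every sample x locus in the registry: one
#' allele at single-copy loci, two at multicopy loci, with length-based
#' designations uniform over the locus reference range and sequences
#' expanded from the reference architecture. Isometric variants substitute
#' one expandable repeat unit with a mutated unit of the same length.
#' Scenario injections replace designated sample x locus genotypes
#' (grey-zone heterozygote, tri-allelic pattern, duplication, deletion)
#' and annotate the low-coverage locus.
#'
#' @param config An [simulation_config()] object.
#' @return Tibble with one row per true allele copy: `sample_id`, `locus`,
#'   `copy`, `repeats`, `partial_nt`, `allele`, `sequence`, `is_variant`,
#'   `anno` (scenario tag or `NA`). Deterministic given the config seed.
#' @export
simulate_true_profiles <- function(config) {
  stopifnot(inherits(config, "ystr_sim_config"))
  registry <- config$registry
  empty <- tibble(
    sample_id = character(), locus = character(), copy = integer(),
    repeats = integer(), partial_nt = integer(), allele = character(),
    sequence = character(), is_variant = logical(), anno = character()
  )
  if (config$n_samples == 0) {
    return(empty)
  }
  set.seed(config$seed)
  params <- config$locus_params
  sc <- config$scenarios
  rows <- vector("list", config$n_samples)
  for (i in seq_len(config$n_samples)) {
    sid <- sprintf("S%03d", i)
    per_locus <- purrr::map(names(registry$loci), function(lname) {
      ld <- registry$loci[[lname]]
      pr <- params[params$locus == lname, ]
      n_copies <- if (ld$copy_number == "multi") 2L else 1L
      reps <- sort(sample(
        seq(ld$ref_allele_range[1], ld$ref_allele_range[2]),
        n_copies,
        replace = TRUE
      ))
      anno <- rep(NA_character_, n_copies)

      if (sc$grey_zone && i == 1L && lname == config$grey_zone_locus) {
        reps <- sort(config$grey_zone_alleles)
        anno <- c(NA, "grey_zone_dropout")
      } else if (sc$triallelic && i == 2L && lname == config$triallelic_locus) {
        reps <- sort(config$triallelic_alleles)
        anno <- rep("triallelic", 3L)
      } else if (sc$duplication && i == 3L &&
        lname == config$duplication_locus) {
        mid <- round(mean(ld$ref_allele_range))
        reps <- c(mid, mid + 2L)
        anno <- rep("duplication", 2L)
      } else if (sc$deletion && i == 4L && lname == config$deletion_locus) {
        return(NULL)
      }
      if (sc$low_coverage && lname == config$low_coverage_locus) {
        anno <- rep("low_coverage", length(reps))
      }
      n_copies <- length(reps)
      seqs <- purrr::map_chr(reps, ~ expand_reference(ld, .x))
      variant <- runif(n_copies) < pr$seq_variant_rate & is.na(anno)
      seqs[variant] <- purrr::map_chr(
        seqs[variant], ~ substitute_variant_unit(.x, ld)
      )
      tibble(
        sample_id = sid, locus = lname, copy = seq_len(n_copies),
        repeats = as.integer(reps), partial_nt = 0L,
        allele = allele_label(reps), sequence = seqs,
        is_variant = variant, anno = anno
      )
    })
    rows[[i]] <- bind_rows(per_locus)
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) empty else out
}

# replace one interior expandable unit with its mutated counterpart,
# preserving total length (isometric by construction)
substitute_variant_unit <- function(sequence, locus_def) {
  unit <- locus_def$repeat_unit_length
  s <- sequence_units(sequence, unit)
  exp_motifs <- expandable_motifs(locus_def)
  idx <- which(s$units %in% exp_motifs)
  if (length(idx) < 3) {
    return(sequence)
  }
  # pick an interior unit of the run so the substitution is unambiguous
  i <- idx[ceiling(length(idx) / 2)]
  s$units[i] <- mutate_motif(s$units[i])
  paste0(paste(s$units, collapse = ""), s$residue)
}

# truncated-normal draw (lower bound only), via inverse-CDF so the RNG
# stream length is independent of the acceptance rate
rtnorm_lower <- function(n, mean, sd, lower = 0.1) {
  if (n == 0) {
    return(numeric())
  }
  p0 <- stats::pnorm(lower, mean, sd)
  u <- runif(n, p0, 1)
  stats::qnorm(u, mean, sd)
}

#' Render a CE genotype peak table
#'
#' Converts true profiles into a GeneMapper-style tab-delimited peak
#' table: each true allele becomes a parent peak with lognormal height,
#' each parent spawns an n-1 minus-stutter peak (and n+1 / n-2nt peaks
#' where the locus distribution says so) at the drawn percentage of the
#' parent height, multicopy heterozygote copies are scaled by a Beta
#' balance draw on the higher-molecular-weight copy, and occasional noise
#' peaks stay strictly below the peak amplitude threshold. Peaks landing
#' on the same allele position (e.g. the stutter of an adjacent allele)
#' are summed, as a fragment analyser would see them.
#'
#' @param profiles Output of [simulate_true_profiles()].
#' @param config The same [simulation_config()].
#' @return Tibble with columns `sample_id`, `locus`, `allele`, `size_bp`,
#'   `height_rfu`, `dye`.
#' @export
render_ce_table <- function(profiles, config) {
  stopifnot(inherits(config, "ystr_sim_config"))
  set.seed(config$seed + 1L)
  registry <- config$registry
  pat <- registry$thresholds$pat_rfu
  empty <- tibble(
    sample_id = character(), locus = character(), allele = character(),
    size_bp = numeric(), height_rfu = numeric(), dye = character()
  )
  if (nrow(profiles) == 0) {
    return(empty)
  }
  keys <- distinct(profiles, .data$sample_id, .data$locus)
  out <- purrr::pmap(keys, function(sample_id, locus) {
    ld <- registry$loci[[locus]]
    pr <- config$locus_params[config$locus_params$locus == locus, ]
    prof <- profiles[
      profiles$sample_id == sample_id & profiles$locus == locus,
    ]
    unit <- ld$repeat_unit_length
    sdlog <- sqrt(log(1 + pr$ce_rfu_cv^2))
    meanlog <- log(pr$ce_mean_rfu) - sdlog^2 / 2
    h <- rlnorm(nrow(prof), meanlog, sdlog)
    if (nrow(prof) > 1) {
      # scale each higher-MW copy of a heterozygote by a balance draw
      b <- rbeta(nrow(prof) - 1, config$ilb_beta_shape1,
        config$ilb_beta_shape2)
      h[-1] <- h[1] * pmin(b, 1)
    }
    peaks <- list()
    put <- function(label, height) {
      peaks[[length(peaks) + 1]] <<- tibble(allele = label, height = height)
    }
    for (k in seq_len(nrow(prof))) {
      put(prof$allele[k], h[k])
      r_minus <- rtnorm_lower(
        1, pr$minus_stutter_mean_pct, pr$minus_stutter_sd_pct
      )
      put(
        shift_allele_label(prof$repeats[k], prof$partial_nt[k], unit, -unit),
        h[k] * r_minus / 100
      )
      if (pr$plus_stutter_mean_pct > 0) {
        r_plus <- rtnorm_lower(
          1, pr$plus_stutter_mean_pct, pr$plus_stutter_sd_pct
        )
        put(
          shift_allele_label(prof$repeats[k], prof$partial_nt[k], unit, unit),
          h[k] * r_plus / 100
        )
      }
      if (pr$minus2_stutter_mean_pct > 0) {
        r_m2 <- rtnorm_lower(1, pr$minus2_stutter_mean_pct, 0.5)
        put(
          shift_allele_label(prof$repeats[k], prof$partial_nt[k], unit, -2L),
          h[k] * r_m2 / 100
        )
      }
    }
    tbl <- bind_rows(peaks) |>
      filter(!is.na(.data$allele)) |>
      group_by(.data$allele) |>
      summarise(height_rfu = sum(.data$height), .groups = "drop")
    if (runif(1) < config$noise_peak_rate) {
      noise_rep <- ld$ref_allele_range[1] - 2L
      noise_lab <- allele_label(noise_rep)
      if (!noise_lab %in% tbl$allele && noise_rep > 1) {
        tbl <- bind_rows(tbl, tibble(
          allele = noise_lab, height_rfu = runif(1, 25, pat - 10)
        ))
      }
    }
    parsed <- parse_allele_label(tbl$allele)
    tbl |>
      mutate(
        sample_id = sample_id, locus = locus,
        size_bp = ld$size_offset_bp +
          allele_nt(parsed$repeats, parsed$partial_nt, unit),
        height_rfu = round(.data$height_rfu),
        dye = ld$dye
      ) |>
      filter(.data$height_rfu >= 1) |>
      select(
        "sample_id", "locus", "allele", "size_bp", "height_rfu", "dye"
      )
  })
  bind_rows(out) |> arrange(.data$sample_id, .data$locus, .data$size_bp)
}

#' Render an MPS sequence-read table
#'
#' Converts true profiles into a UAS-style per-locus sequence-read table.
#' Locus depth is negative-binomial; multicopy heterozygote reads are
#' split by a Beta balance draw; each parent sequence spawns an n-1
#' (and optionally n+1) stutter sequence, derived by removing or adding
#' one expandable repeat unit, at the drawn percentage of the parent
#' reads. Identical sequences are aggregated. The grey-zone scenario
#' forces the designated dropout allele to a read count between the
#' recalculated analytical and interpretation thresholds; the
#' low-coverage scenario drives its locus below callable depth. A
#' per-sample total-read table (Y-STR reads plus a background draw for
#' the rest of the panel) accompanies the read table for the sample gate.
#'
#' @inheritParams render_ce_table
#' @return A list of two tibbles: `reads` (`sample_id`, `locus`,
#'   `sequence`, `reads`, `typed_flag`) and `samples` (`sample_id`,
#'   `total_reads`).
#' @export
render_mps_table <- function(profiles, config) {
  stopifnot(inherits(config, "ystr_sim_config"))
  set.seed(config$seed + 2L)
  registry <- config$registry
  empty <- tibble(
    sample_id = character(), locus = character(), sequence = character(),
    reads = integer(), typed_flag = character()
  )
  if (nrow(profiles) == 0) {
    return(list(
      reads = empty,
      samples = tibble(sample_id = character(), total_reads = numeric())
    ))
  }
  keys <- distinct(profiles, .data$sample_id, .data$locus)
  out <- purrr::pmap(keys, function(sample_id, locus) {
    ld <- registry$loci[[locus]]
    pr <- config$locus_params[config$locus_params$locus == locus, ]
    prof <- profiles[
      profiles$sample_id == sample_id & profiles$locus == locus,
    ]
    mean_doc <- if (any(prof$anno %in% "low_coverage")) {
      config$low_coverage_mean_doc
    } else {
      pr$mean_doc
    }
    depth <- rnbinom(1, mu = mean_doc, size = pr$doc_dispersion)
    if (depth == 0 || mean_doc == 0) {
      return(NULL)
    }
    w <- rep(1, nrow(prof))
    if (nrow(prof) > 1) {
      b <- rbeta(nrow(prof) - 1, config$ilb_beta_shape1,
        config$ilb_beta_shape2)
      w[-1] <- pmin(b, 1)
    }
    parent_reads <- pmax(round(depth * w / sum(w)), 1)
    gz <- which(prof$anno %in% "grey_zone_dropout")
    if (length(gz)) {
      parent_reads[gz] <- config$grey_zone_dropout_reads
      parent_reads[-gz] <- config$grey_zone_parent_reads
    }
    recs <- list()
    put <- function(sequence, reads, flag) {
      recs[[length(recs) + 1]] <<- tibble(
        sequence = sequence, reads = reads, typed_flag = flag
      )
    }
    for (k in seq_len(nrow(prof))) {
      put(prof$sequence[k], parent_reads[k], "YES")
      r_minus <- rtnorm_lower(
        1, pr$minus_stutter_mean_pct, pr$minus_stutter_sd_pct
      )
      st <- stutter_sequence(prof$sequence[k], ld, "minus")
      st_reads <- round(parent_reads[k] * r_minus / 100)
      if (!is.na(st) && st_reads >= 1) put(st, st_reads, "NO")
      if (pr$plus_stutter_mean_pct > 0) {
        r_plus <- rtnorm_lower(
          1, pr$plus_stutter_mean_pct, pr$plus_stutter_sd_pct
        )
        stp <- stutter_sequence(prof$sequence[k], ld, "plus")
        stp_reads <- round(parent_reads[k] * r_plus / 100)
        if (!is.na(stp) && stp_reads >= 1) put(stp, stp_reads, "NO")
      }
    }
    bind_rows(recs) |>
      group_by(.data$sequence) |>
      summarise(
        reads = sum(.data$reads),
        typed_flag = if (any(.data$typed_flag == "YES")) "YES" else "NO",
        .groups = "drop"
      ) |>
      mutate(sample_id = sample_id, locus = locus) |>
      select("sample_id", "locus", "sequence", "reads", "typed_flag")
  })
  reads <- bind_rows(out)
  if (nrow(reads)) {
    reads <- arrange(
      reads, .data$sample_id, .data$locus, desc(.data$reads), .data$sequence
    )
  } else {
    reads <- empty
  }
  samples <- tibble(sample_id = sprintf("S%03d", seq_len(config$n_samples)))
  ystr_reads <- reads |>
    group_by(.data$sample_id) |>
    summarise(ystr = sum(.data$reads))
  samples <- samples |>
    left_join(ystr_reads, by = "sample_id") |>
    mutate(
      total_reads = round(
        (.data$ystr %|0|% 0) +
          rnorm(n(), config$background_reads_mean, config$background_reads_sd)
      )
    ) |>
    select("sample_id", "total_reads")
  list(reads = reads, samples = samples)
}

`%|0|%` <- function(x, y) ifelse(is.na(x), y, x)

#' Simulate a complete paired CE/MPS dataset
#'
#' Convenience wrapper drawing true profiles and rendering both platform
#' tables in one call.
#'
#' @inheritParams simulate_true_profiles
#' @return List with elements `profiles`, `ce`, `mps_reads`,
#'   `mps_samples`.
#' @export
simulate_paired_tables <- function(config = simulation_config()) {
  profiles <- simulate_true_profiles(config)
  ce <- render_ce_table(profiles, config)
  mps <- render_mps_table(profiles, config)
  list(
    profiles = profiles, ce = ce,
    mps_reads = mps$reads, mps_samples = mps$samples
  )
}
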