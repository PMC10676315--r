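#' Platform threshold configuration
#'
#' Bundles the global calling thresholds shared by all loci: the CE peak
#' amplitude threshold (PAT) and heterozygous/homozygous minimum peak
#' heights, the MPS total-sample read gate, the per-locus read basis used
#' when recalculating analytical/interpretation thresholds, and the
#' intra-locus balance thresholds per platform.
#'
#' @param pat_rfu CE peak amplitude threshold in RFU (default 175).
#' @param ce_het_rfu Minimum height for a heterozygous CE call (default 100).
#' @param ce_hom_rfu Minimum height for a homozygous (single-peak) CE call
#'   (default 200).
#' @param mps_sample_read_gate Minimum total sample reads for an MPS run to
#'   be kept (default 85000).
#' @param mps_recalc_basis_reads Minimum per-locus read basis for AT/IT
#'   recalculation (default 650).
#' @param ilb_threshold_ce,ilb_threshold_mps Intra-locus balance thresholds
#'   in percent (defaults 65 and 60).
#' @return A named list of class `ystr_thresholds`.
#' @export
threshold_config <- function(pat_rfu = 175, ce_het_rfu = 100,
                             ce_hom_rfu = 200,
                             mps_sample_read_gate = 85000,
                             mps_recalc_basis_reads = 650,
                             ilb_threshold_ce = 65,
                             ilb_threshold_mps = 60) {
  vals <- list(
    pat_rfu = as.numeric(pat_rfu),
    ce_het_rfu = as.numeric(ce_het_rfu),
    ce_hom_rfu = as.numeric(ce_hom_rfu),
    mps_sample_read_gate = as.numeric(mps_sample_read_gate),
    mps_recalc_basis_reads = as.numeric(mps_recalc_basis_reads),
    ilb_threshold_ce = as.numeric(ilb_threshold_ce),
    ilb_threshold_mps = as.numeric(ilb_threshold_mps)
  )
  if (any(purrr::map_lgl(vals, ~ !is.finite(.x) || .x <= 0))) {
    abort("all threshold values must be strictly positive")
  }
  if (vals$ce_het_rfu > vals$ce_hom_rfu) {
    abort("ce_het_rfu must not exceed ce_hom_rfu")
  }
  structure(vals, class = "ystr_thresholds")
}

#' Load a Y-STR locus registry
#'
#' Reads a structured-text (YAML) locus configuration with a global
#' `defaults:` section (threshold configuration plus default AT/IT
#' percentages) and one entry per locus under `loci:`. Per-locus keys
#' override the global defaults. A ready-made registry covering the 19
#' shared loci ships with the package; see [default_registry()].
#'
#' @param source Path to a YAML file, or an already-parsed list with
#'   elements `defaults` and `loci`.
#' @return An object of class `ystr_registry`: a list with elements
#'   `loci` (named list of locus definitions) and `thresholds`
#'   (a [threshold_config()]).
#' @examples
#' reg <- default_registry()
#' names(reg$loci)
#' @export
load_locus_registry <- function(source) {
  raw <- if (is.character(source)) yaml::read_yaml(source) else source
  if (!is.list(raw) || is.null(raw$loci)) {
    abort("registry config must contain a 'loci' section")
  }
  nm <- names(raw$loci)
  if (is.null(nm) || anyDuplicated(nm)) {
    abort("duplicate (or missing) locus names in registry config")
  }
  defaults <- raw$defaults %||% list()
  thr_keys <- names(formals(threshold_config))
  thresholds <- do.call(
    threshold_config,
    defaults[intersect(names(defaults), thr_keys)]
  )
  at_default <- as.numeric(defaults$at_pct %||% 1.5)
  it_default <- as.numeric(defaults$it_pct %||% 4.5)
  loci <- purrr::imap(
    raw$loci,
    ~ new_locus_definition(.x, .y, at_default, it_default)
  )
  structure(list(loci = loci, thresholds = thresholds),
    class = "ystr_registry"
  )
}

new_locus_definition <- function(x, name, at_default, it_default) {
  required <- c("copy_number", "repeat_unit_length", "motif_structure")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(paste0(
      "locus '", name, "' is missing fields: ",
      paste(missing, collapse = ", ")
    ))
  }
  unit <- as.integer(x$repeat_unit_length)
  if (!unit %in% 3:6) {
    abort(paste0("locus '", name, "': repeat_unit_length must be 3-6"))
  }
  if (!x$copy_number %in% c("single", "multi")) {
    abort(paste0("locus '", name, "': copy_number must be single or multi"))
  }
  counted_idx <- as.integer(x$counted_blocks %||% seq_along(x$motif_structure))
  blocks <- purrr::imap(x$motif_structure, function(b, i) {
    if (is.null(b$motif) || stringr::str_detect(b$motif, "[^ACGT]")) {
      abort(paste0("locus '", name, "': block motif must be an A/C/G/T string"))
    }
    list(
      motif = b$motif,
      expandable = isTRUE(b$expandable),
      ref_repeats = as.integer(b$ref_repeats %||% 1L),
      counted = i %in% counted_idx
    )
  })
  if (!any(purrr::map_lgl(blocks, "expandable"))) {
    abort(paste0("locus '", name, "': at least one block must be expandable"))
  }
  at_pct <- as.numeric(x$at_pct %||% at_default)
  it_pct <- as.numeric(x$it_pct %||% it_default)
  if (!(at_pct > 0 && at_pct < it_pct && it_pct < 100)) {
    abort(paste0(
      "locus '", name, "': thresholds must satisfy 0 < AT < IT < 100 ",
      "(got AT = ", at_pct, ", IT = ", it_pct, ")"
    ))
  }
  structure(list(
    name = name,
    copy_number = x$copy_number,
    repeat_unit_length = unit,
    motif_structure = blocks,
    counted_blocks = counted_idx,
    ref_allele_range = as.integer(x$ref_allele_range %||%
      c(blocks[[1]]$ref_repeats - 2L, blocks[[1]]$ref_repeats + 2L)),
    at_pct = at_pct,
    it_pct = it_pct,
    ce_minus_stutter_filter = as.numeric(x$ce_minus_stutter_filter %||% 15),
    ce_plus_stutter_filter = as.numeric(x$ce_plus_stutter_filter %||% NA),
    ce_minus2_stutter_filter = as.numeric(x$ce_minus2_stutter_filter %||% NA),
    mps_stutter_filter = as.numeric(x$mps_stutter_filter %||% 20),
    ce_analyzed = !isFALSE(x$ce_analyzed),
    mps_analyzed = !isFALSE(x$mps_analyzed),
    dye = x$dye %||% "FAM",
    size_offset_bp = as.numeric(x$size_offset_bp %||% 100)
  ), class = "locus_definition")
}

#' The shipped default registry
#'
#' Loads the locus configuration installed with the package: 19 shared
#' Y-STR loci, 18 of which are analyzed on both platforms (DYS392 is
#' flagged `mps_analyzed = FALSE`, reflecting its unreliable sequencing
#' coverage).
#'
#' @return An `ystr_registry`.
#' @export
default_registry <- function() {
  load_locus_registry(
    system.file("extdata", "ystr_registry.yaml",
      package = "ystrconcord", mustWork = TRUE
    )
  )
}

#' Write a registry back to structured text
#'
#' Serialises a registry so that [load_locus_registry()] on the written
#' file reproduces an identical object (round-trip property).
#'
#' @param registry An `ystr_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_locus_registry <- function(registry, path) {
  stopifnot(inherits(registry, "ystr_registry"))
  loci <- purrr::map(registry$loci, function(ld) {
    out <- list(
      copy_number = ld$copy_number,
      repeat_unit_length = ld$repeat_unit_length,
      motif_structure = purrr::map(
        ld$motif_structure,
        ~ list(
          motif = .x$motif, expandable = .x$expandable,
          ref_repeats = .x$ref_repeats
        )
      ),
      counted_blocks = ld$counted_blocks,
      ref_allele_range = ld$ref_allele_range,
      at_pct = ld$at_pct,
      it_pct = ld$it_pct,
      ce_minus_stutter_filter = ld$ce_minus_stutter_filter,
      mps_stutter_filter = ld$mps_stutter_filter,
      ce_analyzed = ld$ce_analyzed,
      mps_analyzed = ld$mps_analyzed,
      dye = ld$dye,
      size_offset_bp = ld$size_offset_bp
    )
    if (!is.na(ld$ce_plus_stutter_filter)) {
      out$ce_plus_stutter_filter <- ld$ce_plus_stutter_filter
    }
    if (!is.na(ld$ce_minus2_stutter_filter)) {
      out$ce_minus2_stutter_filter <- ld$ce_minus2_stutter_filter
    }
    out
  })
  yaml::write_yaml(
    list(defaults = unclass(registry$thresholds), loci = loci),
    path
  )
  invisible(path)
}

#' Validate a locus registry
#'
#' Report-only check of registry invariants. Unlike [load_locus_registry()],
#' which rejects structurally invalid configs outright, this collects
#' soft violations (e.g. an MPS stutter filter outside the usual 15-50%
#' band) so a registry edited for a special study can still be inspected.
#'
#' @param registry An `ystr_registry`.
#' @return A tibble with columns `locus`, `severity` (`"error"` or
#'   `"warning"`) and `message`; zero rows for the shipped defaults.
#' @export
validate_registry <- function(registry) {
  stopifnot(inherits(registry, "ystr_registry"))
  out <- list()
  add <- function(locus, severity, message) {
    out[[length(out) + 1]] <<- tibble(
      locus = locus, severity = severity, message = message
    )
  }
  if (length(registry$loci) == 0) {
    add(NA_character_, "error", "no loci in registry")
  }
  for (ld in registry$loci) {
    if (ld$mps_stutter_filter < 15 || ld$mps_stutter_filter > 50) {
      add(ld$name, "warning", paste0(
        "mps_stutter_filter ", ld$mps_stutter_filter,
        "% is outside the default 15-50% range"
      ))
    }
    if (!is.na(ld$ce_plus_stutter_filter) &&
      ld$ce_plus_stutter_filter >= ld$ce_minus_stutter_filter) {
      add(ld$name, "warning", "plus-stutter filter >= minus-stutter filter")
    }
    rng <- ld$ref_allele_range
    if (length(rng) != 2 || rng[1] > rng[2]) {
      add(ld$name, "error", "ref_allele_range must be an increasing pair")
    }
  }
  if (length(out) == 0) {
    return(tibble(
      locus = character(), severity = character(), message = character()
    ))
  }
  bind_rows(out)
}

#' @exportS3Method tibble::as_tibble
as_tibble.ystr_registry <- function(x, ...) {
  purrr::map_dfr(x$loci, function(ld) {
    tibble(
      locus = ld$name,
      copy_number = ld$copy_number,
      repeat_unit_length = ld$repeat_unit_length,
      n_blocks = length(ld$motif_structure),
      ref_min = ld$ref_allele_range[1],
      ref_max = ld$ref_allele_range[2],
      at_pct = ld$at_pct,
      it_pct = ld$it_pct,
      ce_minus_stutter_filter = ld$ce_minus_stutter_filter,
      ce_plus_stutter_filter = ld$ce_plus_stutter_filter,
      mps_stutter_filter = ld$mps_stutter_filter,
      ce_analyzed = ld$ce_analyzed,
      mps_analyzed = ld$mps_analyzed
    )
  })
}

#' @export
print.ystr_registry <- function(x, ...) {
  cat(
    "<ystr_registry>", length(x$loci), "loci;",
    sum(purrr::map_lgl(x$loci, "mps_analyzed")), "MPS-analyzed\n"
  )
  print(as_tibble(x), ...)
  invisible(x)
}

# loci analyzed on the requested platform(s)
analyzed_loci <- function(registry, platform = c("both", "CE", "MPS")) {
  platform <- match.arg(platform)
  keep <- purrr::map_lgl(registry$loci, function(ld) {
    switch(platform,
      both = ld$ce_analyzed && ld$mps_analyzed,
      CE = ld$ce_analyzed,
      MPS = ld$mps_analyzed
    )
  })
  names(registry$loci)[keep]
}

registry_locus <- function(registry, name) {
  ld <- registry$loci[[name]]
  if (is.null(ld)) abort(paste0("locus '", name, "' is not in the registry"))
  ld
}

check_known_loci <- function(loci, registry) {
  unknown <- setdiff(unique(loci), names(registry$loci))
  if (length(unknown)) {
    abort(paste0(
      "loci absent from the registry: ", paste(unknown, collapse = ", ")
    ))
  }
  invisible(TRUE)
}
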