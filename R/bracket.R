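#' Bracketed sequence nomenclature for STR repeat regions
#'
#' `bracket_sequence()` converts a repeat-region nucleotide string into the
#' bracketed repeat notation used in forensic sequence nomenclature
#' (e.g. `"[TCTG]3 [TCTA]9"`), derives the length-based allele designation,
#' and flags isometric variants, i.e. sequences that differ from the
#' reference repeat architecture for the same length allele.
#'
#' Parsing first attempts a strict match against the locus motif blocks
#' (non-expandable blocks must occur at their reference copy number,
#' expandable blocks absorb a maximal run). Sequences carrying internal
#' motif substitutions - the typical isometric variant - fail the strict
#' parse and are handled by a unit-grid parse that run-length encodes
#' consecutive repeat units; this is only valid when every block of the
#' locus is counted towards the allele designation, which holds for all
#' shipped locus definitions. Residual nucleotides shorter than one repeat
#' unit become the microvariant suffix (allele `x.partial_nt`).
#'
#' @param sequence Repeat-region string over A/C/G/T.
#' @param locus_def A locus definition from a [load_locus_registry()]
#'   registry.
#' @return One-row tibble: `locus`, `sequence`, `bracket`, `repeats`,
#'   `partial_nt`, `allele`, `is_variant`.
#' @seealso [expand_bracket()], [expand_reference()]
#' @examples
#' reg <- default_registry()
#' ld <- reg$loci[["DYS19"]]
#' bracket_sequence(strrep("TAGA", 14), ld)
#' @export
bracket_sequence <- function(sequence, locus_def) {
  check_sequence(sequence)
  unit <- locus_def$repeat_unit_length

  parsed <- strict_block_parse(sequence, locus_def)
  if (is.null(parsed)) {
    if (!all(purrr::map_lgl(locus_def$motif_structure, "counted"))) {
      abort(paste0(
        "sequence at locus '", locus_def$name,
        "' does not match the reference block structure and the locus has ",
        "uncounted blocks; refusing to guess an allele designation"
      ))
    }
    parsed <- unit_grid_parse(sequence, unit)
  }

  repeats <- parsed$counted_repeats
  partial <- parsed$partial_nt
  ref <- tryCatch(
    expand_reference(locus_def, repeats, partial),
    error = function(e) NA_character_
  )
  tibble(
    locus = locus_def$name,
    sequence = sequence,
    bracket = parsed$bracket,
    repeats = repeats,
    partial_nt = partial,
    allele = allele_label(repeats, partial),
    is_variant = is.na(ref) || !identical(sequence, ref)
  )
}

#' Expand a bracketed repeat string back into nucleotides
#'
#' Inverse of the notation produced by [bracket_sequence()]: bracketed
#' tokens `[MOTIF]n` are repeated `n` times and a bare trailing token is
#' appended verbatim (microvariant residue).
#'
#' @param bracket Bracket-notation string, e.g. `"[TCTA]11 TC"`.
#' @return Nucleotide string.
#' @export
expand_bracket <- function(bracket) {
  tokens <- stringr::str_split_1(stringr::str_trim(bracket), "\\s+")
  pieces <- purrr::map_chr(tokens, function(tok) {
    m <- stringr::str_match(tok, "^\\[([ACGT]+)\\]([0-9]+)$")
    if (!is.na(m[1, 1])) {
      return(strrep(m[1, 2], as.integer(m[1, 3])))
    }
    if (stringr::str_detect(tok, "^[ACGT]+$")) {
      return(tok)
    }
    abort(paste0("cannot parse bracket token '", tok, "'"))
  })
  paste(pieces, collapse = "")
}

#' Reference repeat-region sequence for a length allele
#'
#' Expands the locus reference architecture at a given allele designation:
#' non-expandable blocks occur at their reference copy number, the
#' expandable block absorbs the remaining counted repeats, and a
#' microvariant residue is appended as a prefix of the last expandable
#' motif.
#'
#' @inheritParams bracket_sequence
#' @param repeats Integer length-based allele (full repeats).
#' @param partial_nt Residual nucleotides for microvariants (default 0).
#' @return Nucleotide string.
#' @export
expand_reference <- function(locus_def, repeats, partial_nt = 0L) {
  blocks <- locus_def$motif_structure
  expandable <- purrr::map_lgl(blocks, "expandable")
  counted <- purrr::map_lgl(blocks, "counted")
  if (!any(expandable)) abort("locus has no expandable block")
  fixed_counted <- sum(purrr::map_int(
    blocks[counted & !expandable], "ref_repeats"
  ))
  # distribute remaining counted repeats over expandable blocks: the first
  # expandable block flexes, any further expandable blocks stay at reference
  extra_exp <- which(expandable)[-1]
  extra_counted <- sum(purrr::map_int(
    blocks[intersect(extra_exp, which(counted))], "ref_repeats"
  ))
  flex <- repeats - fixed_counted - extra_counted
  if (flex < 1) {
    abort(paste0(
      "allele ", allele_label(repeats, partial_nt), " is too short for the ",
      "reference architecture of locus '", locus_def$name, "'"
    ))
  }
  first_exp <- which(expandable)[1]
  counts <- purrr::map_int(blocks, "ref_repeats")
  counts[first_exp] <- flex
  body <- paste(
    purrr::map2_chr(blocks, counts, ~ strrep(.x$motif, .y)),
    collapse = ""
  )
  if (partial_nt > 0) {
    last_exp <- blocks[[utils::tail(which(expandable), 1)]]
    body <- paste0(body, substr(last_exp$motif, 1L, partial_nt))
  }
  body
}

# ---- internal parsing helpers -----------------------------------------------

check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence) ||
    nchar(sequence) == 0) {
    abort("sequence must be a single non-empty string")
  }
  if (stringr::str_detect(sequence, "[^ACGT]")) {
    abort("sequence contains characters outside A/C/G/T")
  }
  invisible(sequence)
}

# count leading copies of `motif` in `s`
leading_repeats <- function(s, motif) {
  w <- nchar(motif)
  n <- 0L
  while (nchar(s) >= w && substr(s, 1L, w) == motif) {
    s <- substr(s, w + 1L, nchar(s))
    n <- n + 1L
  }
  n
}

strict_block_parse <- function(sequence, locus_def) {
  unit <- locus_def$repeat_unit_length
  s <- sequence
  counts <- integer(length(locus_def$motif_structure))
  for (i in seq_along(locus_def$motif_structure)) {
    b <- locus_def$motif_structure[[i]]
    n <- leading_repeats(s, b$motif)
    if (!b$expandable) {
      if (n < b$ref_repeats) {
        return(NULL)
      }
      n <- b$ref_repeats
    } else if (n < 1L) {
      return(NULL)
    }
    counts[i] <- n
    s <- substr(s, n * nchar(b$motif) + 1L, nchar(s))
  }
  if (nchar(s) >= unit) {
    return(NULL)
  }
  counted <- purrr::map_lgl(locus_def$motif_structure, "counted")
  bracket <- paste(purrr::map2_chr(
    locus_def$motif_structure, counts,
    ~ paste0("[", .x$motif, "]", .y)
  ), collapse = " ")
  if (nchar(s) > 0) bracket <- paste(bracket, s)
  list(
    counted_repeats = sum(counts[counted]),
    partial_nt = nchar(s),
    bracket = bracket
  )
}

unit_grid_parse <- function(sequence, unit) {
  n_units <- nchar(sequence) %/% unit
  partial <- nchar(sequence) %% unit
  if (n_units < 1L) abort("sequence shorter than one repeat unit")
  units <- stringr::str_sub(
    sequence,
    seq(1L, by = unit, length.out = n_units),
    seq(unit, by = unit, length.out = n_units)
  )
  r <- rle(units)
  bracket <- paste(
    paste0("[", r$values, "]", r$lengths),
    collapse = " "
  )
  if (partial > 0) {
    bracket <- paste(bracket, stringr::str_sub(sequence, n_units * unit + 1L))
  }
  list(counted_repeats = n_units, partial_nt = partial, bracket = bracket)
}

# split a repeat region into unit-grid tokens; residue returned separately
sequence_units <- function(sequence, unit) {
  n_units <- nchar(sequence) %/% unit
  list(
    units = if (n_units > 0) {
      stringr::str_sub(
        sequence,
        seq(1L, by = unit, length.out = n_units),
        seq(unit, by = unit, length.out = n_units)
      )
    } else {
      character()
    },
    residue = stringr::str_sub(sequence, n_units * unit + 1L)
  )
}

expandable_motifs <- function(locus_def) {
  purrr::map_chr(
    purrr::keep(locus_def$motif_structure, "expandable"), "motif"
  )
}

# sequence-exact stutter relation on the unit grid: returns
# "minus_one_repeat" if `child` equals `parent` with exactly one
# expandable-motif unit removed, "plus_one_repeat" for one such unit added,
# otherwise NA. Microvariant residues must match exactly.
stutter_relation <- function(parent, child, locus_def) {
  unit <- locus_def$repeat_unit_length
  p <- sequence_units(parent, unit)
  c_ <- sequence_units(child, unit)
  if (!identical(p$residue, c_$residue)) {
    return(NA_character_)
  }
  exp_motifs <- expandable_motifs(locus_def)
  if (length(c_$units) == length(p$units) - 1L &&
    units_one_deletion(p$units, c_$units, exp_motifs)) {
    return("minus_one_repeat")
  }
  if (length(c_$units) == length(p$units) + 1L &&
    units_one_deletion(c_$units, p$units, exp_motifs)) {
    return("plus_one_repeat")
  }
  NA_character_
}

# TRUE iff `short` equals `long` with exactly one unit (an expandable motif)
# deleted at some position
units_one_deletion <- function(long, short, motifs) {
  n <- length(short)
  if (length(long) != n + 1L) {
    return(FALSE)
  }
  if (n == 0L) {
    return(long[1] %in% motifs)
  }
  same <- long[seq_len(n)] == short
  i <- if (all(same)) n + 1L else which(!same)[1]
  if (!long[i] %in% motifs) {
    # a run of identical units admits several deletion points; try them all
    cand <- which(long %in% motifs)
    for (j in cand) {
      if (identical(long[-j], short)) {
        return(TRUE)
      }
    }
    return(FALSE)
  }
  identical(long[-i], short)
}

# deterministic one-repeat-shorter / -longer stutter product of a parent
# sequence: delete (or duplicate) the last unit matching an expandable motif
stutter_sequence <- function(parent, locus_def, direction = c("minus", "plus")) {
  direction <- match.arg(direction)
  unit <- locus_def$repeat_unit_length
  p <- sequence_units(parent, unit)
  idx <- which(p$units %in% expandable_motifs(locus_def))
  if (length(idx) == 0) {
    return(NA_character_)
  }
  i <- utils::tail(idx, 1)
  units <- if (direction == "minus") {
    if (length(p$units) == 1L) character() else p$units[-i]
  } else {
    append(p$units, p$units[i], after = i)
  }
  if (length(units) == 0L) {
    return(NA_character_)
  }
  paste0(paste(units, collapse = ""), p$residue)
}
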