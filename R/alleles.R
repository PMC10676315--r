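#' Parse STR allele labels
#'
#' Forensic STR alleles are labelled by their repeat count, with microvariants
#' written as `repeats.partial` where `partial` is the number of residual
#' nucleotides beyond a whole repeat (e.g. `"13.2"` is 13 full repeats plus
#' 2 nt). This parses labels into their integer components.
#'
#' @param x Character vector of allele labels such as `"14"` or `"13.2"`.
#' @return A tibble with columns `label`, `repeats` (integer) and
#'   `partial_nt` (integer, 0 for whole-repeat alleles). Labels that do not
#'   parse yield `NA` components.
#' @examples
#' parse_allele_label(c("14", "13.2"))
#' @export
parse_allele_label <- function(x) {
  x <- as.character(x)
  m <- stringr::str_match(x, "^([0-9]+)(?:\\.([0-9]))?$")
  repeats <- as.integer(m[, 2])
  tibble(
    label = x,
    repeats = repeats,
    partial_nt = ifelse(is.na(repeats), NA_integer_,
      ifelse(is.na(m[, 3]), 0L, as.integer(m[, 3]))
    )
  )
}

#' Build an allele label from repeat components
#'
#' @param repeats Integer vector of full repeat counts.
#' @param partial_nt Integer vector of residual nucleotides (0 for whole
#'   repeats).
#' @return Character vector of labels (`"14"`, `"13.2"`, ...).
#' @export
allele_label <- function(repeats, partial_nt = 0L) {
  partial_nt <- rep_len(partial_nt, length(repeats))
  ifelse(partial_nt > 0,
    paste0(repeats, ".", partial_nt),
    as.character(repeats)
  )
}

# total repeat-region length in nucleotides for an allele at a given unit size
allele_nt <- function(repeats, partial_nt, unit) repeats * unit + partial_nt

# label of the allele whose repeat-region is `delta_nt` nucleotides away,
# given the locus repeat-unit length; returns NA if the result is negative
shift_allele_label <- function(repeats, partial_nt, unit, delta_nt) {
  nt <- allele_nt(repeats, partial_nt, unit) + delta_nt
  out <- rep(NA_character_, length(nt))
  ok <- !is.na(nt) & nt > 0
  out[ok] <- allele_label(nt[ok] %/% unit, nt[ok] %% unit)
  out
}
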