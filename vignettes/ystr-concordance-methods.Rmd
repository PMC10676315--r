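---
title: "Methods: CE vs MPS Y-STR concordance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CE vs MPS Y-STR concordance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrconcord)
```

## The problem

Forensic laboratories moving Y-chromosome short tandem repeat (Y-STR)
typing from capillary electrophoresis (CE) to massively parallel
sequencing (MPS) need evidence that the two technologies call the same
genotypes. The two platforms measure different physical quantities - CE
measures fragment length as dye fluorescence (RFU) per peak, MPS counts
reads per repeat-region sequence - and each applies its own thresholds
and artifact filters before an allele is reported. A concordance study
therefore has to reconcile, per sample and per locus: the called
alleles, the PCR stutter artifacts and their percentage ratios, the
balance between the two alleles of multicopy loci, and the extra
resolution MPS gains from sequence-level variation.

`ystrconcord` implements that comparison as a reusable pipeline: a
locus registry describing repeat architectures and thresholds, callers
for both platforms, stutter and balance analytics, a per-locus
concordance classifier, and a synthetic-data generator so the whole
chain is testable without access to casework data (which, for this
class of study, is never deposited).

## Platform calling models

### CE

Peaks below the peak amplitude threshold (PAT, default 175 RFU) are
noise. A surviving peak one repeat unit below (n-1) or above (n+1) a
taller surviving peak, or two nucleotides below it (n-2nt), is labelled
stutter when its height ratio is at or below the locus stutter filter.
After stutter filtering, a lone candidate peak must reach 200 RFU to be
called (homozygous-style single-allele call, the expected state for a
haploid single-copy Y-STR); two or more candidates must each reach
100 RFU. The PAT is applied before stutter logic: stutter ratios are
only meaningful between peaks that are real signal.

The calling order (thresholds after stutter filtering) is a documented
choice; vendor software does not state the order, and the alternative
ordering changes no call in the simulated conditions because the
100/200 RFU minima sit well below typical parent signal.

### MPS

Samples are kept only when the total sample read count reaches 85,000
reads. Per locus, the analytical threshold (AT) and interpretation
threshold (IT) percentages - 1.5% and 4.5% by default, with per-locus
overrides (5.0/15 at DYS389II, 3.3/10 at DYS448 and DYS635) - are
converted to read counts on a recalculation basis of at least 650
reads, rounded up. This rounding rule is the only one that reproduces
both documented floors: 1.5% and 4.5% of 650 reads are 9.75 and 29.25,
i.e. 10 and 30 reads. The published description admits a second
reading (percentages of the actual locus reads, clamped at the 10/30
floors); both are implemented and selectable
(`recalc_thresholds(method =)`), with `"basis_floor"` the default.
Whether the percentages are taken of total locus reads or of the
maximum-allele reads is also unstated; total locus reads is used.

Sequences below AT are discarded. Sequences strictly between AT and IT
form the *grey zone*: they are surfaced as candidates with a QC flag
but never promoted to calls - adjudication belongs to the concordance
step (in casework, to the operator). Sequences at or above IT are
called unless they are sequence-exact stutters of an already-called
parent: equal to the parent's string with exactly one expandable
repeat unit removed (n-1) or added (n+1), at or below the locus
stutter filter. The same filter value serves both stutter directions,
matching typing software that ships one value per locus; a
per-direction override hook exists in the registry schema. Ties for
the maximum-intensity allele are broken toward the longer allele, then
lexicographically - deterministic and documented. A locus where no
sequence reaches IT is flagged inconclusive (`low_coverage_inc`), the
behaviour that chronically affects DYS392 and removes it from the
default analysis set (`mps_analyzed: false` in the registry).

## Sequence nomenclature and variants

`bracket_sequence()` mechanises the manual review of repeat-region
strings: a strict parse against the locus block structure
(non-expandable blocks at reference copy number, expandable blocks
absorbing a maximal run), falling back to a unit-grid run-length parse
for strings with internal motif substitutions. Residues shorter than
one unit become microvariant designations (13 repeats + 2 nt =
"13.2"). A sequence is an *isometric variant* when it differs from the
reference expansion of its own length allele; at multicopy loci two
called alleles of equal length but different sequence are an
*iso-allele* pair, and a single called variant sequence is a *variant
homozygote*. The allele census counts unique length-based alleles
(union over platforms) per locus plus the additional unique variant
sequences MPS alone resolves.

The shipped registry covers the 19 loci shared by the common CE and
MPS panels with simplified reference architectures (one flexing run,
plus a fixed block where canonical nomenclature uses one). They are
editable YAML fixtures, not a transcription of reference tables - the
test suite deliberately uses toy motifs so correctness never depends on
those entries.

## Stutter analytics

Stutter percentage ratios are stutter signal over parent signal x 100,
heights for CE and reads for MPS. Observations are collected on every
detectable stutter-position signal *regardless of the filter* - the
filter affects calling only - because above-filter stutters are real
and reportable. On CE, a peak one repeat below one called allele and
one repeat above another is assigned the minus interpretation (minus
stutter dominates by an order of magnitude) and flagged ambiguous.

At multicopy loci with called alleles exactly one repeat apart, the
larger allele's n-1 stutter coincides with the smaller allele's peak
and the smaller allele's n+1 stutter with the larger allele's peak;
both are recorded as excluded observations
(`overlaps_smaller_allele` / `overlaps_larger_allele`) and omitted
from all statistics. On MPS the overlap is sequence-mediated: it only
materialises when the adjacent alleles share a sequence type, in which
case the overlapped record's reads are logged as the excluded
observation; a variant-string neighbour produces a separate record and
is excluded on the same length-adjacency rule.

Detection frequency denominators count samples that passed the read
gate and have a called parent allele at the locus on that platform.
Per-locus CE-vs-MPS comparisons use a two-sample t-test, separately
per copy (a/b) at multicopy loci.

## Intra-locus balance

For multicopy heterozygotes the balance is minor/major signal x 100,
flagged below threshold at 65% (CE) or 60% (MPS). Tri-allelic
genotypes are excluded from balance with a logged exclusion.
Platform-level comparison again uses the t-test.

The t-test is implemented directly from the pooled-variance formula
(df = nx + ny - 2) rather than wrapping `stats::t.test()`, because
degenerate groups (both constant) must return a defined result - t = 0
and p = 1 for identical groups - where the wrapped function errors.
`stats::t.test(var.equal = TRUE)` serves as the independent
cross-check in the test suite, and Welch's variant (available via
`var_equal = FALSE`) delegates to it, since the equal-variance
assumption behind the pooled test is not verifiable from summary data.

## Concordance classification

Per sample x locus, on length-based allele sets:

* equal sets -> `concordant`, with pattern notes: two alleles at a
  single-copy locus is a duplication, zero alleles on both platforms a
  deletion, three at a multicopy locus a tri-allelic pattern;
* MPS flagged `low_coverage_inc` -> `excluded_inconclusive`;
* every CE-only allele matches an MPS grey-zone candidate of exactly
  the same length, and MPS called no extra alleles ->
  `apparent_discordant_grey_zone` (the operator-review pattern: a true
  allele whose reads fell between AT and IT, typically from a
  primer-binding-site mutation); near-misses stay `discordant`;
* anything else -> `discordant`.

One boundary needed a decision: a locus with *no* MPS records at all
and no CE call is classified as a concordant deletion, while
`excluded_inconclusive` is reserved for loci where records exist but
none reaches IT. Without that distinction a real deletion would be
indistinguishable from a coverage failure.

## The synthetic-data generator

The generator emulates a 125-donor single-source male study on the
19-locus shared panel; every parameter is a config field and the
defaults are the study conditions:

* **Read depth**: negative binomial per locus (dispersion 8) around
  per-locus means averaging 789 reads, with the documented extremes
  (213 at Y-GATA-H4, 3,091 at DYS438); heavy-tailed locus coverage is
  what an amplicon panel produces.
* **Total sample reads**: per-locus Y-STR reads plus a Normal
  background draw (mean 78,000) standing in for the non-Y content of
  the sequencing panel, giving totals near 93,000 against the
  85,000-read gate. The per-locus table alone cannot carry the
  whole-panel total, so the generator emits a per-sample total table
  alongside it.
* **CE peak heights**: lognormal (mean 2,000 RFU, CV 0.35) - strictly
  positive and right-skewed, the standard shape for fluorescence
  intensity.
* **Stutter ratios**: Normal truncated at zero, means scaling
  inversely with repeat-unit length (14% trinucleotide, 9% tetra, 4%
  penta, 3% hexa), one distribution per locus shared by both
  platforms. The spreads are set so that clean-scenario draws stay
  below the calling filters; platform-specific stutter differences are
  emulated by editing per-platform configs rather than a built-in
  offset.
* **Multicopy balance**: Beta(9, 1.5) applied to the
  higher-molecular-weight copy (mean balance ~86%); the observed
  balance is the draw up to read rounding, so the below-threshold rate
  is the Beta tail probability.
* **Sequence variants**: one interior expandable unit substituted by a
  single-base-mutated unit of the same length - isometric by
  construction - at rate 0.25 at the eight variant-prone loci.
* **Scenario injections** (all on by default, each at a designated
  sample): a grey-zone dropout at the multicopy locus DYS385 a/b
  (genotype 14,19 with the dropout allele forced to 19 reads against
  10/30 thresholds), a balanced tri-allelic 37,38,39 at DYF387S1, a
  duplication at DYS448, a deletion at DYS570, and chronic low
  coverage (mean 25 reads) at DYS392 across all samples.

What the generator does **not** emulate: flanking-region variation,
primer-binding-site mutations as a mechanism (the grey-zone scenario
injects the read-count consequence directly), cross-contamination,
mixtures, degradation, dye pull-up, or platform-specific stutter
biases. Passing tests therefore demonstrate the pipeline's logic under
controlled conditions, not its behaviour on every real-world artifact.

## Numerical choices and problem sizes

Ceiling rounding in threshold recalculation (see above); grey zone as
the open interval (AT, IT), since an allele must *exceed* AT to be
considered and reach IT to be called; stutter draws truncated at zero
via the inverse-CDF so the RNG stream length does not depend on the
acceptance rate (this keeps output byte-identical for a given seed);
empty inputs return typed zero-row tibbles rather than errors
everywhere a report is the contract, and hard errors are reserved for
structural problems (unknown loci, unparseable sequences, invalid
registries).

The test suite exercises the full chain at the study scale of 125
samples x 19 loci (one default-condition run and one clean run, shared
across tests), with unit tests on toy loci sized for hand-derivable
expectations. Parameter recovery is evaluated at stutter means of 5%,
12% and 31% with the CE parent signal raised to 8,000 RFU so the
175-RFU analytical floor does not left-censor the low-ratio draws; at
routine signal levels the CE stutter census is left-truncated, exactly
as it is in real casework.

## Known limitations

* Registry motif structures are simplified; loci whose canonical
  nomenclature interleaves several flexing runs would need additional
  blocks, and the unit-grid fallback assumes every block counts toward
  the allele designation.
* Iso-allele detection relies on the caller having typed both
  sequences; grey-zone iso-alleles are not paired.
* The generator's single stutter distribution per locus cannot produce
  the platform effect a real study measures; the t-test machinery is
  exercised, but its defaults will show no CE/MPS difference.
* The balance Beta is shared by both platforms and all multicopy loci.
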