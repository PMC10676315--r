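# ystrconcord

Concordance analysis of forensic Y-STR genotypes between capillary
electrophoresis (CE) and massively parallel sequencing (MPS).

Forensic laboratories validating MPS against the established CE
workflow need to show, locus by locus, that both technologies report
the same Y-STR genotypes — while accounting for everything that makes
the two readouts different: RFU peaks versus read counts, platform
thresholds, PCR stutter artifacts, multicopy-locus imbalance, and the
sequence-level variation only MPS resolves. `ystrconcord` implements
that comparison as a tested, scriptable pipeline for single-source
male profiles on the 19-locus panel shared by the common CE and MPS
kits.

## What it computes

Per sample × locus, allele calling under each platform's regime:

* **CE** — peaks below the peak amplitude threshold (PAT, 175 RFU) are
  noise; a peak at the n−1 / n+1 / n−2nt position of a taller peak
  with height ratio ≤ the locus stutter filter is stutter; a lone
  candidate needs ≥ 200 RFU, two or more need ≥ 100 RFU each.
* **MPS** — samples need ≥ 85,000 total reads; per locus, the
  analytical and interpretation thresholds AT and IT (1.5% / 4.5%
  defaults, per-locus overrides) are recalculated in reads as
  `ceil(pct × max(locus_reads, 650))`, reproducing the documented
  10- and 30-read floors; reads in the open interval (AT, IT) form the
  *grey zone*, surfaced for review but never auto-called; a sequence
  ≥ IT is called unless it is a sequence-exact stutter (one expandable
  repeat removed/added) of a called parent within the locus filter.

On top of the calls: stutter percentage ratios
(stutter/parent × 100) with multicopy overlap exclusions; ISFG-style
bracketed nomenclature with iso-allele and isometric-variant
detection; intra-locus balance (minor/major × 100, 65% CE / 60% MPS
thresholds, tri-allelic genotypes excluded); a length- and
sequence-based allele census; per-locus concordance status
(`concordant`, `apparent_discordant_grey_zone`,
`excluded_inconclusive`, `discordant`); and pooled-variance Student
t-tests comparing the platforms.

A synthetic-data generator produces paired CE/MPS tables with
negative-binomial coverage, lognormal peak heights, truncated-normal
stutter, Beta-distributed multicopy balance and injectable special
cases (grey-zone dropout, tri-allelic pattern, duplication, deletion,
low-coverage locus), so the full pipeline is testable end to end.

## Worked example

```r
library(ystrconcord)

cfg <- simulation_config(n_samples = 10, seed = 42)
sim <- simulate_paired_tables(cfg)
res <- ystr_concordance(
  sim$ce, sim$mps_reads,
  registry = cfg$registry,
  mps_sample_totals = sim$mps_samples,
  include_unanalyzed = TRUE
)
res
```

```
<ystr_concordance>
  10 samples x 19 loci: 180 concordant, 1 grey-zone, 9 inconclusive, 0 discordant
  100 unique length-based alleles, 20 additional sequence-based
  non-concordant records:
    S001 DYS385 a/b: CE {14,19} vs MPS {14} -> apparent_discordant_grey_zone
    S001 DYS392: CE {12} vs MPS {} -> excluded_inconclusive
    ...
```

The one grey-zone record is the injected dropout case: CE sees the
14,19 heterozygote while the MPS reads for allele 19 (19 reads) exceed
the analytical threshold (10 reads) but not the interpretation
threshold (30 reads) — an apparent, not a true, discordance, left for
operator review. The `excluded_inconclusive` records are the
chronically low-coverage locus DYS392, which never reaches IT and is
excluded from the default cross-platform analysis set
(`mps_analyzed: false` in the registry; drop `include_unanalyzed` to
compare only the 18 reliable loci).

`tidy(res)` returns the per-record concordance tibble, `glance(res)` a
one-row run summary, and `autoplot(res, "stutter" | "balance" |
"concordance")` the standard figures. Threshold arithmetic is exposed
directly:

```r
recalc_thresholds(650)
#> # A tibble: 1 × 3
#>   locus_reads at_reads it_reads
#> 1         650       10       30
```

A thin command-line wrapper ships at `inst/cli/ystr-concord.R`
(`simulate` and `concord` subcommands over the same functions).

## Documentation

The methods vignette
(`vignettes/ystr-concordance-methods.Rmd`) describes the calling
models, the threshold recalculation rules and their admissible
alternative, the stutter and balance definitions, the concordance
classification, what the simulator does and does not emulate, and the
package's numerical choices and limitations.
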