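# Default Y-STR locus registry: the 19 loci shared between a 6-dye CE
# Y-STR multiplex and an MPS forensic panel. Motif structures are
# simplified reference architectures (single flexing repeat run, plus a
# fixed block where the canonical nomenclature uses one); they are
# editable fixtures, not a transcription of the ISFG reference tables.
# Thresholds: analytical (at_pct) / interpretation (it_pct) percentages
# default to 1.5 / 4.5 with per-locus overrides; stutter filters are the
# percentage of the parent signal at or below which an n-1 (or n+1 /
# n-2nt) product is treated as stutter rather than an allele.
defaults:
  pat_rfu: 175
  ce_het_rfu: 100
  ce_hom_rfu: 200
  mps_sample_read_gate: 85000
  mps_recalc_basis_reads: 650
  ilb_threshold_ce: 65
  ilb_threshold_mps: 60
  at_pct: 1.5
  it_pct: 4.5
loci:
  DYS19:
    copy_number: single
    repeat_unit_length: 4
    motif_structure:
    - {motif: TAGA, expandable: true, ref_repeats: 15}
    counted_blocks: [1]
    ref_allele_range: [12, 19]
    ce_minus_stutter_filter: 18.0
    ce_plus_stutter_filter: 6.0
    mps_stutter_filter: 20.0
    dye: VIC
    size_offset_bp: 180
  DYS385 a/b:
    copy_number: multi
    repeat_unit_length: 4
    motif_structure:
    - {motif: GAAA, expandable: true, ref_repeats: 14}
    counted_blocks: [1]
    ref_allele_range: [10, 20]
    ce_minus_stutter_filter: 16.0
    ce_plus_stutter_filter: 6.0
    mps_stutter_filter: 20.0
    dye: FAM
    size_offset_bp: 240
  DYS389I:
    copy_number: single
    repeat_unit_length: 4
    motif_structure:
    - {motif: TCTG, expandable: false, ref_repeats: 3}
    - {motif: TCTA, expandable: true, ref_repeats: 9}
    counted_blocks: [1, 2]
    ref_allele_range: [10, 15]
    ce_minus_stutter_filter: 17.0
    ce_plus_stutter_filter: 6.0
    mps_stutter_filter: 20.0
    dye: FAM
    size_offset_bp: 200
  DYS389II:
    copy_number: single
    repeat_unit_length: 4
    motif_structure:
    - {motif: TCTG, expandable: false, ref_repeats: 4}
    - {motif: TCTA, expandable: true, ref_repeats: 25}
    counted_blocks: [1, 2]
    ref_allele_range: [26, 34]
    at_pct: 5.0
    it_pct: 15.0
    ce_minus_stutter_filter: 20.0
    ce_plus_stutter_filter: 6.0
    mps_stutter_filter: 25.0
    dye: FAM
    size_offset_bp: 240
  DYS390:
    copy_number: single
    repeat_unit_length: 4
    motif_structure:
    - {motif: TCTA, expandable: true, ref_repeats: 24}
    counted_blocks: [1]
    ref_allele_range: [21, 26]
    ce_minus_stutter_filter: 18.0
    ce_plus_stutter_filter: 6.0
    mps_stutter_filter: 20.0
    dye: NED
    size_offset_bp: 150
  DYS391:
    copy_number: single
    repeat_unit_length: 4
    motif_structure:
    - {motif: TCTA, expandable: true, ref_repeats: 11}
    counted_blocks: [1]
    ref_allele_range: [8, 13]
    ce_minus_stutter_filter: 15.0
    ce_plus_stutter_filter: 6.0
    mps_stutter_filter: 20.0
    dye: VIC
    size_offset_bp: 100
  DYS392:
    copy_number: single
    repeat_unit_length: 3
    motif_structure:
    - {motif: TAT, expandable: true, ref_repeats: 13}
    counted_blocks: [1]
    ref_allele_range: [9, 15]
    ce_minus_stutter_filter: 25.0
    mps_stutter_filter: 40.0
    mps_analyzed: false
    dye: NED
    size_offset_bp: 260
  DYS437:
    copy_number: single
    repeat_unit_length: 4
    motif_structure:
    - {motif: TCTA, expandable: true, ref_repeats: 15}
    counted_blocks: [1]
    ref_allele_range: [13, 17]
    ce_minus_stutter_filter: 15.0
    ce_plus_stutter_filter: 6.0
    mps_stutter_filter: 20.0
    dye: PET
    size_offset_bp: 120
  DYS438:
    copy_number: single
    repeat_unit_length: 5
    motif_structure:
    - {motif: TTTTC, expandable: true, ref_repeats: 12}
    counted_blocks: [1]
    ref_allele_range: [8, 14]
    ce_minus_stutter_filter: 10.0
    ce_plus_stutter_filter: 6.0
    mps_stutter_filter: 15.0
    dye: PET
    size_offset_bp: 200
  DYS439:
    copy_number: single
    repeat_unit_length: 4
    motif_structure:
    - {motif: GATA, expandable: true, ref_repeats: 12}
    counted_blocks: [1]
    ref_allele_range: [9, 14]
    ce_minus_stutter_filter: 16.0
    ce_plus_stutter_filter: 6.0
    mps_stutter_filter: 20.0
    dye: VIC
    size_offset_bp: 140
  DYS448:
    copy_number: single
    repeat_unit_length: 6
    motif_structure:
    - {motif: AGAGAT, expandable: true, ref_repeats: 19}
    counted_blocks: [1]
    ref_allele_range: [17, 24]
    at_pct: 3.3
    it_pct: 10.0
    ce_minus_stutter_filter: 10.0
    ce_plus_stutter_filter: 6.0
    mps_stutter_filter: 15.0
    dye: NED
    size_offset_bp: 290
  DYS460:
    copy_number: single
    repeat_unit_length: 4
    motif_structure:
    - {motif: ATAG, expandable: true, ref_repeats: 10}
    counted_blocks: [1]
    ref_allele_range: [7, 12]
    ce_minus_stutter_filter: 16.0
    ce_plus_stutter_filter: 6.0
    mps_stutter_filter: 20.0
    dye: FAM
    size_offset_bp: 110
  DYS481:
    copy_number: single
    repeat_unit_length: 3
    motif_structure:
    - {motif: CTT, expandable: true, ref_repeats: 22}
    counted_blocks: [1]
    ref_allele_range: [17, 28]
    ce_minus_stutter_filter: 30.0
    ce_plus_stutter_filter: 6.0
    mps_stutter_filter: 45.0
    dye: PET
    size_offset_bp: 120
  DYS533:
    copy_number: single
    repeat_unit_length: 4
    motif_structure:
    - {motif: ATCT, expandable: true, ref_repeats: 12}
    counted_blocks: [1]
    ref_allele_range: [9, 14]
    ce_minus_stutter_filter: 15.0
    ce_plus_stutter_filter: 6.0
    mps_stutter_filter: 20.0
    dye: VIC
    size_offset_bp: 200
  DYS570:
    copy_number: single
    repeat_unit_length: 4
    motif_structure:
    - {motif: TTTC, expandable: true, ref_repeats: 17}
    counted_blocks: [1]
    ref_allele_range: [14, 21]
    ce_minus_stutter_filter: 18.0
    ce_plus_stutter_filter: 6.0
    mps_stutter_filter: 20.0
    dye: NED
    size_offset_bp: 230
  DYS576:
    copy_number: single
    repeat_unit_length: 4
    motif_structure:
    - {motif: AAAG, expandable: true, ref_repeats: 18}
    counted_blocks: [1]
    ref_allele_range: [14, 21]
    ce_minus_stutter_filter: 18.0
    ce_plus_stutter_filter: 6.0
    mps_stutter_filter: 20.0
    dye: FAM
    size_offset_bp: 170
  DYS635:
    copy_number: single
    repeat_unit_length: 4
    motif_structure:
    - {motif: TCTA, expandable: true, ref_repeats: 19}
    - {motif: TGTA, expandable: false, ref_repeats: 2}
    counted_blocks: [1, 2]
    ref_allele_range: [19, 25]
    at_pct: 3.3
    it_pct: 10.0
    ce_minus_stutter_filter: 17.0
    ce_plus_stutter_filter: 6.0
    mps_stutter_filter: 20.0
    dye: PET
    size_offset_bp: 160
  DYF387S1:
    copy_number: multi
    repeat_unit_length: 4
    motif_structure:
    - {motif: AAAG, expandable: true, ref_repeats: 37}
    counted_blocks: [1]
    ref_allele_range: [34, 40]
    ce_minus_stutter_filter: 16.0
    ce_plus_stutter_filter: 6.0
    mps_stutter_filter: 20.0
    dye: NED
    size_offset_bp: 210
  Y-GATA-H4:
    copy_number: single
    repeat_unit_length: 4
    motif_structure:
    - {motif: TAGA, expandable: true, ref_repeats: 12}
    counted_blocks: [1]
    ref_allele_range: [10, 14]
    ce_minus_stutter_filter: 15.0
    ce_plus_stutter_filter: 6.0
    mps_stutter_filter: 20.0
    dye: FAM
    size_offset_bp: 130
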