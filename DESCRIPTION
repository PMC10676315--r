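Package: ystrconcord
Title: Concordance Analysis of Y-STR Genotypes Between Capillary
    Electrophoresis and Massively Parallel Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forensic Y-chromosome short tandem repeat (Y-STR)
    concordance studies comparing capillary electrophoresis (CE) genotypes
    with massively parallel sequencing (MPS) calls. Implements
    platform-specific allele calling under peak-amplitude and analytical /
    interpretation threshold regimes, stutter identification and percentage
    ratios with multicopy overlap exclusions, bracketed (ISFG-style)
    sequence nomenclature with iso-allele and isometric variant detection,
    intra-locus balance evaluation, per-locus concordance classification
    including grey-zone adjudication, and paired-platform statistical
    comparisons. A synthetic-data generator produces paired CE peak tables
    and MPS sequence-read tables with configurable coverage, stutter and
    balance structure so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
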