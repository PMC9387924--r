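Package: embryomosaic
Title: Single-Cell Copy-Number Calling and Chromosomal Mosaicism Analysis for Preimplantation Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study chromosomal mosaicism in preimplantation embryos from
    low-coverage single-cell whole-genome sequencing. Starting from per-cell read
    counts in fixed genomic bins, the package corrects GC-content and mappability
    bias, infers integer copy number with a hidden Markov model, filters
    low-quality cells by a windowed variability score, and aggregates per-cell
    karyotypes into embryo-level statistics: mosaicism incidence, mosaic type
    (whole, segmental, complex), meiotic versus mitotic origin of copy-number
    events, trophectoderm versus inner-cell-mass discordance, complementary
    (reciprocal) CNV pairs, and in-silico multi-cell biopsies that demonstrate how
    bulk assays mask balanced mosaic aneuploidy. A synthetic embryo-lineage
    generator with a negative-binomial amplification-noise model provides fully
    ground-truthed cohorts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
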