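Package: fragscreen
Title: PCR-Based Analysis of Cell-Free DNA Fragmentation and Sample Quality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying cell-free DNA (cfDNA) fragmentation with
    PCR-derived data. Implements droplet digital PCR Poisson quantification
    with short/long amplicon fragmentation statistics over open and closed
    chromatin loci, a delta-delta-Cq qPCR score for high-molecular-weight
    genomic DNA contamination calibrated against a standards panel,
    molarity-ratio cross-validation from automated-electrophoresis traces,
    per-region fragment-length summaries from interval data, and the cohort
    statistics used to compare fragmentation between groups. A synthetic-data
    generator emulates plasma cfDNA fragment-length structure (mononucleosomal
    peak, di-/tri-nucleosome degradation ladder, high-molecular-weight
    contamination, sheared calibration standards) so every stage of the
    pipeline can be exercised end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    stats,
    signal,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
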