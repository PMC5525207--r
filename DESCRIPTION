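Package: tmhflanks
Title: Positional Composition Analysis of Transmembrane Helices and Their Flanks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-scale positional analysis of alpha-helical transmembrane
    segments (TMHs) and their flanking regions on a cytoplasmic to
    non-cytoplasmic axis. Reads UniProt-style flat-file topology annotation or
    a plain segment table, orients each helix by the "cytoplasmic" topological
    domain keyword, extracts flanks under four regimes (database-defined with
    or without overlap, viable-flank subsets, and central alignment), and
    derives per-position residue count matrices, absolute relative occurrence
    and relative percentage profiles, net charge curves, and sliding-window
    hydrophobicity profiles. Inside-versus-outside skews (positive-inside and
    negative-not-inside/negative-outside rules), leucine leaflet asymmetry and
    group distribution differences are quantified with rank, chi-square and
    Kolmogorov-Smirnov tests and the sample-size-independent Bahadur slope.
    A seeded synthetic-cohort generator with configurable region-specific
    residue propensities makes every stage testable without database
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
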