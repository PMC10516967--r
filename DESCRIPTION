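Package: ffpecutac
Title: Downstream Analysis of FFPE-CUTAC Chromatin Accessibility Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of antibody-tethered chromatin accessibility
    (CUT&Tag/CUTAC) fragment data from formalin-fixed paraffin-embedded (FFPE)
    samples. Provides genome-size-normalized coverage tracks, fragment-length
    distributions with a 10-bp periodicity score, a simplified Poisson
    sliding-window peak caller with FRiP and downsampling benchmarks, candidate
    cis-regulatory element (cCRE) and gene-level quantification (sums and
    summits), empirical-Bayes moderated differential occupancy with
    voom-style precision weights and Benjamini-Hochberg FDR, per-reference
    contamination accounting with Arrhenius modeling of temperature-dependent
    fragment recovery, and a seeded synthetic fragment generator so every
    stage runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
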