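Package: inoseed
Title: Inosine-Aware miRNA Seed Retargeting and Silencing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of how adenosine-to-inosine (A-to-I) editing inside a
    microRNA seed region redirects target recognition and changes silencing
    efficiency. Builds editing-variant seeds and their mRNA-side 7-mer target
    motifs, scans 3'-UTR sequences into mutually exclusive target groups with
    per-group backgrounds, turns probe-level single-channel microarray
    intensities into gene-level M/A statistics against a mock control, tests
    per-group repression with a fold-change area statistic and Wilcoxon
    rank-sum p-values, and models seed-duplex stability with an inosine-aware
    melting-temperature layer (measured-Tm calibration, nearest-neighbor
    prediction, UV melting-curve Tm extraction, and the miScore statistic).
    Ships a synthetic-data generator that emulates the full study design so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    limma,
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
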