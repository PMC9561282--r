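Package: driploop
Title: Break-Centric DRIP-Seq Analysis of DSB-Induced DNA:RNA Hybrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies DNA:RNA-hybrid (R-loop) formation around sequence-specific
    double-strand breaks from DRIP-seq fragment data. Reads paired-end fragments
    (BEDPE/BED), computes library-size-normalized per-base coverage, summarises
    signal in windows around annotated cut sites, derives damaged/undamaged log2
    fold changes per knockdown arm, classifies sites as knockdown-dependent,
    -independent or -increased by deviation from the identity line, and tests the
    relationship between pre-existing hybrid levels and break-induced hybrid
    formation. Also includes exact small-sample rank-sum, Pearson and paired-t
    tests, DRIP-qPCR percent-input and restriction-protection resection
    quantification, a cross-study proteomic hit-frequency meta-analysis with
    SQ/TQ motif scanning, and a synthetic-data generator that emulates every
    input so the whole pipeline is testable at desk scale.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
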