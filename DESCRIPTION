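Package: duoscreen
Title: Analysis of Combinatorial Dual-Guide CRISPR Knockout Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end analysis of pooled dual-cassette (SpCas9 + SaCas9)
    CRISPR knockout screens run across several growth environments. Parses
    dual-guide sequencing reads into construct-level count matrices, computes
    log2 fold changes against the plasmid DNA baseline, applies a four-step
    quality-control filter cascade, scores single-gene fitness per condition
    as z-scores against the cutting-control null, calls gene-by-environment
    interactions by regression, estimates pairwise genetic-interaction
    pi-scores with a constrained L1 robust additive model and moderated
    guide-level significance, and curates condition-dependent interactions
    with effect-size and artifact filters. A negative-binomial screen
    simulator with full ground truth supports power analysis and
    parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    Matrix,
    limma,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
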