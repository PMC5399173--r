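Package: reosig
Title: Rank-Based Gene-Pair Prognostic Signatures from Within-Sample
    Relative Expression Orderings
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Discovery and application of prognostic gene-pair signatures
    based on within-sample relative expression orderings (REOs) for
    drug-treated cancer cohorts.  A candidate drug-resistance gene screen
    (Spearman correlation against cell-line GI50 values), a univariate Cox
    relapse-free-survival screen with Benjamini-Hochberg control, gene-pair
    REO screening, Harrell C-index forward selection, and a majority-vote
    classifier that calls each sample from its own expression values alone,
    making the signature insensitive to batch effects and monotone
    normalization.  Ships the published six-gene-pair colorectal 5-FU
    signature as a ready-to-use classifier, a multi-omics characterization
    battery (differential expression, copy-number and mutation frequency
    contrasts, methylation-expression correlation, MSI contrast, PPI link
    enrichment, pathway enrichment and prevalence), and a synthetic-data
    generator so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    graphics,
    stats,
    survival,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
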