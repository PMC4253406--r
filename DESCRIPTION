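Package: oncopanel
Title: Tumor-Only Somatic Filtering, Pseudonormal Copy Number and
    Expression Analysis for Cancer Cell-Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for panels of cancer cell lines sequenced
    without matched normal DNA. Approximates somatic mutation calls by
    rejecting variants present in a population allele-frequency database
    and variants recurrent across the panel, while rescuing catalogued
    cancer hotspot mutations; calls per-gene copy number against a
    pseudonormal baseline built from the panel's average capture depths;
    tests two-class differential expression with a negative-binomial
    exact test (common dispersion) and an empirical-Bayes moderated
    t-test; and scores gene-set enrichment with a combined
    Fisher-p/rank-z statistic. Includes a synthetic-data generator with
    known ground truth that emulates a 22-line head-and-neck cancer
    panel, and an end-to-end pipeline producing an oncoprint-style
    summary table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR
Config/testthat/edition: 3
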