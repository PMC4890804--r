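Package: zratioDE
Title: Z-Score/Z-Ratio Microarray Differential Expression with PAGE
    Enrichment and Validation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Differential-expression analysis of probe-level microarray
    intensity data by per-array Z-score normalization and the Z-ratio
    statistic, with a five-criterion significance filter (z-test p,
    absolute Z-ratio, Benjamini-Hochberg false discovery rate,
    non-negative average Z-score, one-way ANOVA p). Includes Parametric
    Analysis of Gene set Enrichment (PAGE) over GMT collections, signed
    three-way Venn partitioning of up- and down-regulated gene lists,
    Pfaffl-method relative qPCR quantification, behavioral discrimination
    preference indices with ANOVA and Fisher LSD post hoc tests, and a
    synthetic-data generator emulating a 4-group, n = 5 expression study
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
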