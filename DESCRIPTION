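Package: telometa
Title: Multilevel Phylogenetic Meta-Analysis of Telomere-Length Heritability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for multilevel meta-analysis of heritability estimates of
    vertebrate telomere length. Curates raw effect sizes (standard-error
    recovery from confidence intervals, parent-offspring regression slope
    conversion, Fisher-z sensitivity transforms), builds phylogenetic
    correlation matrices from Grafen branch lengths, fits a four-component
    random-effects meta-analytic model (study, phylogeny, species, estimate)
    by restricted maximum likelihood with known heteroscedastic sampling
    variances, decomposes heterogeneity (I-squared), runs moderator
    meta-regressions with Wald and likelihood-ratio tests, tests for
    publication bias with a multilevel Egger regression and a time-lag model,
    and quantifies uncertainty with nonparametric percentile bootstrap
    intervals. Includes a synthetic-data generator mirroring the statistical
    structure of published telomere heritability datasets so the whole
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
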