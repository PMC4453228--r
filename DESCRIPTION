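Package: uncles
Title: Consensus Clustering of Genes Across Multiple Expression Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies subsets of genes consistently co-expressed across
    several gene-expression datasets (type A) or specifically co-expressed
    in a positive subset of datasets while poorly co-expressed in a negative
    subset (type B). Hard partitions from k-means, self-organising maps and
    Ward hierarchical clustering are relabelled, averaged into a fuzzy
    consensus partition matrix and binarised with a tunable difference
    threshold. The resulting cluster pool is screened with an M-N scatter
    plot (cluster dispersion versus log gene count) and evaluated against a
    known ground truth with binomial-tail F-P plots. A generator of
    multi-dataset synthetic expression collections with planted clusters,
    per-dataset confounder genes and data-calibrated Gaussian noise is
    included for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
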