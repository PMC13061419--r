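Package: orthocell
Title: Orthologous Cell Type Matching and Expression Conservation Across Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated identification of orthologous cell types across
    species from single-cell RNA-seq count matrices sharing a harmonized gene
    namespace. Provides high-resolution clustering, reciprocal
    rank-correlation classification similarity, hierarchical assignment and
    merging of orthologous cell type clusters, presence-absence expression
    calling with negative-binomial statistics and Firth-penalized logistic
    detection thresholds, a phylogenetically weighted expression conservation
    score on a quartet species tree, marker gene detection with a
    zero-inflated quantile rank-score test, and downstream evaluation of
    marker transferability (rank-biased overlap, top-k intersections, kNN
    marker-panel F1 with bootstrap intervals). Includes a multi-species
    negative-binomial simulator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    ape,
    igraph,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    class
Config/testthat/edition: 3
RoxygenNote: 7.3.3
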