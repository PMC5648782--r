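Package: coexmod
Title: Stage-Resolved Weighted Gene Co-Expression Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds signed-hybrid weighted gene co-expression networks from
    staged bulk RNA-seq count matrices and dissects them into modules: count
    filtering and TMM normalization, robust biweight midcorrelation, soft
    threshold selection by scale-free topology fit, topological overlap,
    dynamic branch cutting with eigengene merging, module-trait association
    with FDR control, intramodular hub gene identification, an exhaustive
    sample-bipartition scan for hidden binary covariates, multiscale
    bootstrap support for sample clustering, classical multidimensional
    scaling, and over-representation analysis with optional length-bias
    correction. Ships a negative-binomial simulator that plants co-expression
    modules with stage-resolved eigengene trajectories and a hidden
    sex-like covariate, so the whole pipeline is testable end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    edgeR,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph,
    withr
Config/testthat/edition: 3
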