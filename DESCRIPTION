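Package: ruvprps
Title: RUV-III Normalization of Bulk RNA-Seq with Pseudo-Replicates of Pseudo-Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removes library-size, tumor-purity and batch variation from bulk
    RNA-seq count matrices using the RUV-III estimator driven by
    pseudo-replicates of pseudo-samples (PRPS). Provides the replicate-structure
    linear algebra and three-step RUV-III fit, PRPS construction for categorical
    batches and continuous unwanted variables, data-driven negative control gene
    selection, a suite of global and gene-level diagnostics of unwanted
    variation (RLE summaries, principal-component regression, Rozeboom vector
    correlation, silhouette, adjusted Rand index, rank-test differential
    expression, partial correlation, rank-based signature scores), a
    negative-binomial simulator that realizes gene-specific library-size
    response classes, purity mixing and plate effects, and sample/gene
    filtering with plain-text readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    cluster,
    mclust,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
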