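Package: mtcn
Title: Relative Mitochondrial DNA Copy Number from Sequencing Read Depth
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates relative mitochondrial DNA (mtDNA) copy number from
    aligned whole-exome or whole-genome sequencing reads as the ratio of
    filtered mitochondrial to nuclear read counts, with a tumor
    purity/ploidy ("effective ploidy") correction and a sequencing-plate
    batch-effect linear model. Provides the downstream cohort statistics
    built on these estimates: paired tumor/normal depletion tests
    (Wilcoxon signed-rank with Benjamini-Hochberg correction),
    cross-platform concordance, covariate correlation, univariate Cox
    survival association, per-gene expression correlation with a
    mean-rank gene-set enrichment test, and somatic-alteration
    association scans (Mann-Whitney U). A synthetic-cohort generator
    with recorded ground truth makes every stage testable without
    controlled-access data.
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
    purrr,
    readr,
    rlang,
    Rsamtools,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
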