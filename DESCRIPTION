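Package: transreg
Title: Systems-Genetics Trans-eQTL Mapping via Co-Expression Modules and Network Centrality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for genome-wide trans-eQTL identification in a
    disease-relevant cell type that reduces the multiple-testing burden by
    restricting the scan to central genes of functionally enriched
    co-expression modules.  Provides probe re-annotation, quantile
    normalization, genotype quality control (missingness, exact
    Hardy-Weinberg test, PCA outlier detection), an additive linear eQTL
    model with covariates and cis/trans classification, weighted
    co-expression module detection via topological overlap, Fisher-exact
    module enrichment, degree/betweenness gene prioritization, and a
    Transcript Complexity Value (TCV) procedure for comparing cis/trans
    regulatory architecture between two cell types over
    recombination-hotspot-delimited loci.  A synthetic-data module
    generates genotype, expression, annotation and network inputs with
    planted structure so every stage is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    igraph,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
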