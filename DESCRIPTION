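Package: AKPtools
Title: Anna Karenina Principle Testing and Diet-Microbiome Variation Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying inter-individual gut microbiome variation
    and its drivers in clinical cohorts. Implements intra-group Ruzicka
    similarity (C-index) collections with Wilcoxon and permutation tests for
    Anna Karenina principle (AKP) and anti-AKP effects of binary exposures;
    hierarchical food-classification trees with tree-based dietary diversity
    (Chao1, Shannon, Gini-Simpson, unweighted and weighted UniFrac);
    Procrustes/PROTEST coupling of dietary and microbiome ordinations;
    zero-aware (hurdle-encoded) microbial co-abundance networks with
    connectivity comparison; PERMANOVA, alpha-diversity linear models and
    two-class LEfSe-style differential abundance; and a synthetic-data
    generator with planted AKP/anti-AKP structure and tunable diet-microbiome
    coupling so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    ape,
    glmnet,
    igraph,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    jsonlite,
    phyloseq,
    testthat (>= 3.0.0),
    vegan,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
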