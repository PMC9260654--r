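Package: particleSuccession
Title: Community-Assembly Inference for Particle-Colonization Succession
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical toolkit for inferring the assembly processes behind
    microbial succession on marine model particles from amplicon count tables.
    Provides Dirichlet-multinomial mixture community typing with
    Laplace-approximated model evidence, a Hierarchical Dirichlet Process
    neutral-model test with an empirical pseudo p-value (complete and local
    variants), phylogenetic turnover statistics (phylogenetic isometric
    log-ratio balances, Mantel correlograms over temporal distance classes,
    abundance-weighted beta-mean-nearest-taxon distance and beta-nearest-taxon
    index with a tip-shuffle null), differential gene-pathway proportion tests
    (Welch and multi-group ANOVA with post-hoc contrasts), and per-taxon
    zero-inflated negative binomial models that classify taxa and matched
    isolates into life strategies. A synthetic-data module generates count
    tables, trees, metadata and gene profiles with the statistical structure
    each stage assumes, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    ape,
    Biostrings,
    biomformat
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    picante,
    glmmTMB,
    jsonlite
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
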