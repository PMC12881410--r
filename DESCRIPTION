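Package: snpdag
Title: Causal Graph Discovery for De-Confounded SNP Prioritization in
    Autotetraploid GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Screens allele-dosage markers (0-4) for direct trait effects
    with cross-fitted double machine learning on a partially linear model,
    using genotype principal components as confounding proxies; stabilises
    the screen across repeated cross-fitting splits; learns a causal graph
    over the selected markers and the trait with a PC-stable algorithm and
    Fisher's Z conditional-independence tests; enforces the
    genotype-to-phenotype edge direction and extracts the ancestral
    subgraph; and classifies markers into direct parent SNPs (the trait's
    Markov blanket) and upstream hub SNPs (high out-degree regulators).
    Includes an autotetraploid cohort simulator with planted causal
    architecture (admixed subpopulations, LD blocks, hub-mediator chains,
    a structure-linked confounder), quality control and spatial BLUP
    utilities, predictive validation of marker sets, structure-recovery
    metrics, and an end-to-end command-line pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    glmnet,
    igraph,
    jsonlite,
    lme4,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
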