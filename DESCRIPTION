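Package: spprOmics
Title: Correlating Gene Expression and the Proteome with Specific Protein
    Production Rate in Chemostat Cultures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: System-wide analysis of chemostat cultivations of a
    protein-producing filamentous fungus. Computes specific rates and yields
    from steady-state cultivation measurements, correlates per-gene log2
    expression with the specific extracellular protein production rate (SPPR)
    with Storey q-value false discovery rate control, detects chromosomal
    clusters of co-correlated adjacent genes with permutation-test support and
    tests their conservation in other genomes by sliding-window InterPro
    domain matching, scores reporter metabolites and finds enriched molecular
    paths on a bipartite metabolic network with a color-coding search and
    weight-shuffling nulls, transfers metabolic reactions across species by
    bidirectional best hits, classifies transcript-protein fold-change pairs
    and their translational control efficiency ratios, and calibrates
    cross-platform expression measurements by AIC model selection. A
    synthetic-data module generates all pipeline inputs with planted,
    recoverable structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    rtracklayer,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
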