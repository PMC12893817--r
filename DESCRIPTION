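Package: pansv
Title: Pangenome Construction and Population Structural-Variant Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds syntelog-based, graph-based and linear pangenomes from a
    set of annotated genomes, genotypes structural variants (SVs) across a
    population of accessions, and runs the downstream population-genetic
    analyses (PCA, neighbour-joining trees, allele-frequency-difference
    selection scans, Weir-Cockerham Fst and windowed nucleotide diversity).
    Alignment primitives are maximal-unique-match anchors chained with
    MUMmer-style parameters; between-anchor gaps are classified into
    insertion, deletion and divergent-allele SVs in the style of
    Assemblytics. A synthetic-data module simulates annotated genomes,
    derived accessions with planted SVs, short-read sets and population
    genotype matrices with known truth, so every stage of the pipeline can
    be validated against planted events.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
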