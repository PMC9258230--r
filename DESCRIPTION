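Package: archfam
Title: Protein Families, Co-Occurrence Modules and Genome Clustering for
    Microbial Pangenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds protein families from all-vs-all protein sequence
    similarity using a two-step procedure (greedy set cover over a filtered
    sequence similarity network, then Markov clustering of a
    probability-times-coverage weighted subfamily graph), detects modules of
    co-occurring families in a genome-by-family presence/absence matrix by
    cutting a Jaccard-distance dendrogram, assigns each module a taxonomic
    distribution, scores family quality against functional annotations
    (consistency, admixture, signal-peptide/transmembrane/hypothetical
    classification), and compares family-content genome clustering with a
    reference phylogeny via cophenetic correlation. Includes genome
    quality rules based on single-copy gene profiles and a synthetic
    pangenome generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    igraph,
    ape,
    vegan,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
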