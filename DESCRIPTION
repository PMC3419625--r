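Package: geneRecon
Title: Reconciliation of Gene Model Predictions Between Genome Assembly Versions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for reconciling the gene model predictions of two assembly
    versions of the same genome. Cross-version sequence matches are filtered at
    high stringency, assembled into a bipartite match graph and classified into
    a cardinality taxonomy (one-to-one, redundant, overlap, split, merged,
    to-split, multiple), with protein evidence used to resolve artificial
    chimeras and to propose split corrections. Matched pairs are further
    analysed positionally (placement transitions, chromosome reassignments,
    block inversions from gene-order runs), unified into a non-redundant gene
    set under a source priority order, and annotated against a hierarchical
    functional-category catalog. A synthetic assembly-pair generator plants
    known edit events (splits, merges, tandem expansions, chimeric fusions,
    inversions, relocations, unplacements) so that every classification step
    can be scored against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    data.table,
    igraph,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Genetics, Annotation, Alignment, ComparativeGenomics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
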