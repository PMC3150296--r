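Package: ontosim
Title: Semantic Similarity of Ontology Terms and Genes over 'is-a' DAGs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for semantic similarity over ontologies restricted to
    'is-a' relationships, such as the Disease Ontology. Parses OBO 1.2 flat
    files into validated directed acyclic graphs, propagates gene annotations
    to compute per-term information content, and offers ten term-term
    similarity measures (Resnik, Lin, Jiang-Conrath, Relevance, graph
    information content, simIC, the GraSM disjunctive-common-ancestor variants
    of Resnik/Lin/Jiang-Conrath, and the Wang edge-weight measure). Gene-gene
    similarity is derived from annotation term sets by five aggregation
    methods (Max, Mean, funSimMax, funSimAvg, best-match average). Also
    included: hypergeometric term enrichment with filter/depth candidate
    selection and FDR control, similarity-driven module detection by
    average-linkage clustering with static or adaptive gap-based dendrogram
    cutting plus permutation significance, DAG subgraph extraction for
    visualization, and seeded synthetic generators for ontologies, annotation
    corpora and planted-partition similarity matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
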