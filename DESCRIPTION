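Package: netalignr
Title: Evaluation and Unification of Global Protein Network Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores pairwise global alignments of protein-protein interaction
    networks with nine quality measures (node coverage, edge correctness,
    induced conserved sub-structure, symmetric sub-structure S3, largest
    conserved component, and KEGG/GO annotation-overlap scores), quantifies
    agreement between alignments, ranks aligners by competition ranking with
    averaged ranks, and unifies several one-to-one alignments into a
    many-to-many mapping with soft clustering, hypergeometric enrichment with
    Benjamini-Hochberg correction, and annotation-transfer consistency.
    Includes a synthetic generator of network pairs with planted alignments
    and annotations for testing and benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
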