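Package: taxocat
Title: Taxonomy Comparison, Multi-Label Maximum-Entropy Document
    Categorization and Guided-Search Query Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with document classification hierarchies such
    as the International Patent Classification (IPC) and the Medical Subject
    Headings (MeSH).  Loads MeSH descriptor XML and a tab-separated taxonomy
    dialect into a common forest representation with an artificial root,
    computes structural statistics and shortest-path annotation distances,
    and profiles how class codes are co-assigned to documents.  Assigns
    additional classes to documents with one-vs-rest binary maximum-entropy
    (regularized logistic) classifiers over bag-of-words features, trained
    with round-robin negative sampling and evaluated by ratio-preserving
    cross-validation.  Supports guided search through class co-occurrence
    statistics with Jaccard ranking, classifier feature-overlap analysis,
    enumeration extraction from class definitions, ontology term matching
    and sibling expansion.  Includes a seeded synthetic-data generator so
    the whole pipeline is testable without proprietary corpora, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    withr,
    xml2
Suggests:
    glmnet,
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
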