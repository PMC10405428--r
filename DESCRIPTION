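Package: cardphen
Title: Collection-Based Reformulation of Cardinality Phenotypes in
    Phenotype Ontologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for working with cardinality (amount and absence)
    phenotype classes in entity-quality (EQ) formalised phenotype
    ontologies.  Detects EQ logical definitions whose quality concerns the
    amount of a cell type, rewrites them over maximal collections of
    entities (collection classes with nominal individuals, a materialised
    collection partonomy, dual absence definitions and grouping classes),
    and computes the entailed subsumption hierarchy before and after the
    rewrite with a pattern-specific fragment classifier verified against a
    naive structural-subsumption saturation oracle.  Quantifies the effect
    of the revised hierarchy on phenotype-similarity based gene-disease
    association ranking using information content, Resnik similarity,
    best-match-average profile similarity and pooled ROC AUC.  Ships seeded
    synthetic fixture generators and readers/writers for OBO and OWL
    functional-style syntax subsets so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
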