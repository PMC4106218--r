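Package: omicstore
Title: A Document-Oriented Store for Multi-Level Systems-Biology Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An embedded, transactional document store for multi-level
    systems-biology data built on a BioPAX-derived class hierarchy. Biological
    entities (chromosomes, genes, transcripts, proteins, compounds, complexes)
    and interactions (conversions, molecular and genetic interactions, control
    events) are kept in two separate document collections with referential
    integrity, indexing and atomic multi-record inserts. Parsers populate the
    store from standard flat formats (FASTA, GFF3-style gene tables,
    BioGRID-like interaction tables, GAF annotations, OBO term graphs) with an
    auditable identifier-ambiguity exclusion rule. Query helpers include
    GO-constrained signaling-path detection over protein-protein interaction
    networks and kinase-to-transcription-factor-to-gene-to-reaction regulon
    traversal. A deterministic synthetic fixture generator with a ground-truth
    manifest makes the whole pipeline testable without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    jsonlite,
    tibble,
    Biostrings,
    rtracklayer,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
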