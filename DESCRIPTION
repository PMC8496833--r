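Package: predigree
Title: Predicate Genealogy Mining for 510(k) Medical Device Summaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs and analyses the predicate ancestry of medical
    devices cleared through the US FDA 510(k) pathway. Parses device summary
    documents into indications-for-use and device-description sections,
    extracts predicate citations, builds the directed predicate genealogy
    graph, scores substantial equivalence between device pairs by cosine
    similarity of bag-of-words or corpus-trained word-embedding document
    vectors, and links Total Product Life Cycle style complaint and recall
    surveillance tables to the genealogy. Includes a synthetic corpus
    generator with planted genealogy, mutation-controlled text similarity
    and heavy-tailed complaint counts, so every pipeline stage is testable
    without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
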