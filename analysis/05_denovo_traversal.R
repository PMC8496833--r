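#!/usr/bin/env Rscript
# Stage 5: genealogy traversal from a De Novo device.
#
# Two traversals, exported as Sankey node/link JSON with similarity edge
# weights: (a) the published nitric-oxide (product code MRN) lineage
# rooted at K974562/DEN000001, using the published similarity column;
# (b) the largest synthetic De Novo lineage, weighted with the
# bag-of-words scores from stage 3.
library(predigree)

lin <- mrn_lineage()
g <- graph_from_edges(lin)
sub <- traverse_from(g, "K974562")
cat("Published MRN lineage:", nrow(sub), "edges,",
    length(unique(c(sub$predicate_id, sub$descendant_id))), "devices\n")
cat("Direct descendants of K061901:", descendant_count(g, "K061901"), "\n")
sankey <- export_sankey(sub, data.frame(predicate_id = lin$predicate_id,
                                        descendant_id = lin$descendant_id,
                                        value = lin$similarity))
jsonlite::write_json(sankey, "results/sankey_mrn_DEN000001.json",
                     auto_unbox = TRUE, digits = NA)
unscored <- sum(!vapply(sankey$links, `[[`, logical(1), "scored"))
cat("Sankey links:", length(sankey$links), "(", unscored,
    "unscored: summaries not public )\n")

corpus_dir <- "results/corpus"
metadata <- read.csv(file.path(corpus_dir, "metadata.csv"),
                     stringsAsFactors = FALSE)
docs <- parse_corpus_dir(file.path(corpus_dir, "summaries"))
graph <- build_graph(metadata, docs)
scores <- read.csv("results/edge_scores_bow.csv", stringsAsFactors = FALSE)
comb <- scores[scores$section == "combined" & scores$scorable == 1, ]
roots <- grep("^DEN", metadata$device_id, value = TRUE)
sizes <- vapply(roots, function(r) nrow(traverse_from(graph, r)), integer(1))
big <- roots[which.max(sizes)]
sub2 <- traverse_from(graph, big)
sk2 <- export_sankey(sub2, data.frame(predicate_id = comb$id_b,
                                      descendant_id = comb$id_a,
                                      value = comb$value))
jsonlite::write_json(sk2, sprintf("results/sankey_synthetic_%s.json", big),
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("Largest synthetic lineage: root %s, %d edges -> %s\n",
            big, nrow(sub2), sprintf("results/sankey_synthetic_%s.json", big)))
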