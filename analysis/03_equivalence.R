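#!/usr/bin/env Rscript
# Stage 3: substantial-equivalence scoring.
#
# Scores every predicate edge with bag-of-words cosine similarity over the
# two summary sections, summarises per-device equivalence by decision
# year, and trains the 500-dimensional shallow word embedding on the full
# token corpus as the alternative scoring route (persisted for reuse).
library(predigree)

corpus_dir <- "results/corpus"
metadata <- read.csv(file.path(corpus_dir, "metadata.csv"),
                     stringsAsFactors = FALSE)
docs <- parse_corpus_dir(file.path(corpus_dir, "summaries"))
graph <- build_graph(metadata, docs)

scores <- score_edges(graph, docs, "bow")
write.csv(scores, "results/edge_scores_bow.csv", row.names = FALSE)
comb <- scores[scores$section == "combined" & scores$scorable == 1, ]
cat(sprintf("Scored %d edges (bow); combined similarity mean %.3f, IQR [%.3f, %.3f]\n",
            nrow(comb), mean(comb$value),
            quantile(comb$value, 0.25), quantile(comb$value, 0.75)))

years <- equivalence_by_year(graph, scores)
write.csv(years, "results/equivalence_by_year.csv", row.names = FALSE)
cat(sprintf("Per-year equivalence: %d years; median of yearly medians %.3f, range [%.3f, %.3f]\n",
            nrow(years), median(years$median), min(years$median),
            max(years$median)))

streams <- unlist(lapply(docs, `[[`, "tokens"), recursive = FALSE)
model <- train_embeddings(streams, dimension = 500, seed = 20260927L)
save_embeddings(model, "results/embeddings.txt")
emb_scores <- score_edges(graph, docs, "embedding", model)
write.csv(emb_scores, "results/edge_scores_embedding.csv", row.names = FALSE)
ec <- emb_scores[emb_scores$section == "combined" & emb_scores$scorable == 1, ]
cat(sprintf("Embedding route: %d-word vocabulary; combined similarity mean %.3f\n",
            length(model$vocabulary), mean(ec$value)))
cat(sprintf("Rank agreement between bow and embedding edge scores: spearman %.3f\n",
            cor(comb$value, ec$value, method = "spearman")))
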