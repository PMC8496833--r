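#!/usr/bin/env Rscript
# Stage 1: simulate the study corpus.
#
# Generates the default synthetic 510(k) corpus: 500 devices over
# 1997-2020, 12 De Novo-rooted product-code lineages, per-edge word
# mutation rates in [0.05, 0.5], heavy-tailed complaint counts with two
# planted outlier product codes and eight Class-1-recalled devices.
# Everything downstream reads the files written here.
library(predigree)

out <- "results/corpus"
cfg <- generator_config(seed = 20260927L)
corp <- generate_corpus(cfg)
write_corpus(corp, out)

te <- corp$ground_truth$true_edges
cat("Simulated", nrow(corp$metadata), "devices,", nrow(te), "predicate edges\n")
cat("Predicate-count distribution (per non-root device):\n")
print(table(table(te$descendant_id)))
cat("Planted outlier product codes:",
    paste(corp$ground_truth$outlier_procodes, collapse = ", "), "\n")
cat("Class-1-recalled devices:",
    paste(corp$ground_truth$recalled_ids, collapse = ", "), "\n")
cat("Corpus written under", out, "\n")
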