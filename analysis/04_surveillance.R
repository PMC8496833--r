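#!/usr/bin/env Rscript
# Stage 4: post-market surveillance.
#
# Ranks product codes by complaint-to-device ratio, writes the
# log-scaled complaints-versus-recalls scatter table, and compares the
# Class-1-recalled devices to marketed devices by text similarity --
# first within their own product codes, then against unrelated codes.
library(predigree)

corpus_dir <- "results/corpus"
truth <- jsonlite::fromJSON(file.path(corpus_dir, "ground_truth.json"))
metadata <- read.csv(file.path(corpus_dir, "metadata.csv"),
                     stringsAsFactors = FALSE)
docs <- parse_corpus_dir(file.path(corpus_dir, "summaries"))

stats <- load_surveillance(file.path(corpus_dir, "surveillance.csv"))
ratio <- sort(complaint_device_ratio(stats), decreasing = TRUE)
cat("Top complaint-to-device ratios:\n")
print(round(head(ratio, 4), 1))
outliers <- identify_outliers(stats, k = 2)
cat("Top-2 outlier codes:", paste(outliers, collapse = ", "),
    "| planted:", paste(truth$outlier_procodes, collapse = ", "), "\n")
writeLines(outliers, "results/outlier_procodes.txt")
write.csv(scatter_table(stats), "results/scatter_table.csv",
          row.names = FALSE)

recalled <- truth$recalled_ids
same_code <- setdiff(
  metadata$device_id[metadata$product_code %in% truth$outlier_procodes],
  recalled)
within <- recalled_vs_marketed(recalled, same_code, docs)
cat(sprintf("Recalled vs marketed, same codes: overall mean %.3f; all below 0.5: %s\n",
            within$overall_mean, within$below_threshold))
other <- metadata$device_id[!metadata$product_code %in% truth$outlier_procodes]
across <- recalled_vs_marketed(recalled, other, docs)
cat(sprintf("Recalled vs marketed, unrelated codes: overall mean %.3f; all below 0.5: %s\n",
            across$overall_mean, across$below_threshold))
jsonlite::write_json(
  list(within_code = list(overall_mean = within$overall_mean,
                          below_threshold = within$below_threshold),
       across_codes = list(overall_mean = across$overall_mean,
                           below_threshold = across$below_threshold)),
  "results/recalled_vs_marketed.json", auto_unbox = TRUE, digits = NA)
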