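write_surv <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

test_that("surveillance tables load, validate and round-trip", {
  corp <- small_corpus()
  stats <- load_surveillance(file.path(small_dir(), "surveillance.csv"))
  expect_equal(stats, corp$surveillance, ignore_attr = TRUE)
  # empty file with header
  empty <- load_surveillance(write_surv(corp$surveillance[0, ]))
  expect_equal(nrow(empty), 0)
  # missing column is fatal
  broken <- corp$surveillance
  broken$device_count <- NULL
  expect_error(load_surveillance(write_surv(broken)), "device_count")
  # malformed rows are rejected individually with diagnostics
  bad <- corp$surveillance
  bad$device_complaints[2] <- -5
  bad$device_count[3] <- 0          # but has complaints
  expect_warning(kept <- load_surveillance(write_surv(bad)), "rejected 2")
  expect_equal(nrow(kept), nrow(bad) - 2)
  expect_length(attr(kept, "rejected"), 2)
})

test_that("complaint-to-device ratio is plain arithmetic with flagged zeros", {
  df <- data.frame(product_code = c("AAA", "BBB"), device_count = c(50, 10),
                   device_complaints = c(100, 0),
                   patient_complaints = c(80, 0),
                   recalls_class1 = 0L, recalls_class2 = 0L,
                   recalls_class3 = 0L)
  expect_equal(complaint_device_ratio(df), c(AAA = 2, BBB = 0))
  expect_equal(complaint_device_ratio(df, "patient"), c(AAA = 1.6, BBB = 0))
  df$device_count[2] <- 0
  expect_warning(r <- complaint_device_ratio(df), "zero devices")
  expect_true(is.na(r["BBB"]))
})

test_that("outlier identification is a deterministic top-k", {
  corp <- small_corpus()
  stats <- corp$surveillance
  found <- identify_outliers(stats, k = 2)
  expect_setequal(found, corp$ground_truth$outlier_procodes)
  # matches a brute-force sort, at every k
  ratio <- stats$device_complaints / stats$device_count
  total <- stats$device_complaints + stats$patient_complaints
  brute <- stats$product_code[order(-ratio, -total, stats$product_code)]
  for (k in c(1, 3, nrow(stats))) {
    expect_equal(identify_outliers(stats, k), brute[seq_len(k)])
  }
  # stable under row permutation
  set.seed(2)
  perm <- stats[sample(nrow(stats)), ]
  expect_equal(identify_outliers(perm, 4), identify_outliers(stats, 4))
  expect_error(identify_outliers(stats, nrow(stats) + 1), "exceeds")
  # ties broken by total complaints then code
  tie <- data.frame(product_code = c("ZZZ", "AAA", "MMM"),
                    device_count = 10L,
                    device_complaints = 100L,
                    patient_complaints = c(5L, 5L, 9L),
                    recalls_class1 = 0L, recalls_class2 = 0L,
                    recalls_class3 = 0L)
  expect_equal(identify_outliers(tie, 3), c("MMM", "AAA", "ZZZ"))
})

test_that("recalled-vs-marketed comparison reports means and the threshold flag", {
  docs <- small_docs()
  corp <- small_corpus()
  md <- corp$metadata
  recalled <- corp$ground_truth$recalled_ids
  outlier_codes <- corp$ground_truth$outlier_procodes
  marketed_same <- setdiff(md$device_id[md$product_code %in% outlier_codes],
                           recalled)
  cmp <- recalled_vs_marketed(recalled, marketed_same, docs)
  expect_equal(dim(cmp$matrix), c(length(recalled), length(marketed_same)))
  # means match brute-force row averages
  expect_equal(cmp$per_recalled_mean, rowMeans(cmp$matrix))
  expect_equal(cmp$overall_mean, mean(cmp$matrix))
  # a device compared against a set containing itself scores 1 with itself
  self_cmp <- recalled_vs_marketed(recalled[1], recalled[1], docs)
  expect_equal(unname(self_cmp$matrix[1, 1]), 1)
  expect_false(self_cmp$below_threshold)
  wide <- recalled_vs_marketed(recalled, recalled, docs)
  expect_equal(unname(diag(wide$matrix)), rep(1, length(recalled)))
  # marketed devices from unrelated codes share no template vocabulary
  other <- md$device_id[!md$product_code %in% outlier_codes]
  cross <- recalled_vs_marketed(recalled, other, docs)
  expect_true(cross$below_threshold)
  expect_lt(cross$overall_mean, 0.2)
  # flag is monotone in the threshold
  t0 <- max(cross$per_recalled_mean) + 0.01
  expect_true(recalled_vs_marketed(recalled, other, docs,
                                   threshold = t0 + 0.2)$below_threshold)
  expect_error(recalled_vs_marketed(character(), other, docs), "non-empty")
  # unparsable summaries are excluded and counted
  docs2 <- docs
  docs2[[recalled[1]]]$parse_status <- "unreadable"
  cmp2 <- recalled_vs_marketed(recalled, other, docs2)
  expect_equal(cmp2$n_excluded, 1)
  expect_equal(nrow(cmp2$matrix), length(recalled) - 1)
})

test_that("scatter table is the log-scaled long format of the stats", {
  stats <- small_corpus()$surveillance
  tab <- scatter_table(stats)
  expect_equal(nrow(tab), 3 * nrow(stats))
  # zero complaints map to log value 0
  zero <- data.frame(product_code = "QQQ", device_count = 5L,
                     device_complaints = 0L, patient_complaints = 0L,
                     recalls_class1 = 1L, recalls_class2 = 0L,
                     recalls_class3 = 0L)
  tz <- scatter_table(zero)
  expect_equal(tz$log10_device_complaints, rep(0, 3))
  # values match brute-force recomputation
  for (i in sample(nrow(tab), 10)) {
    row <- tab[i, ]
    src <- stats[stats$product_code == row$product_code, ]
    expect_equal(row$recall_count,
                 src[[paste0("recalls_class", row$recall_class)]])
    expect_equal(row$log10_device_complaints,
                 log10(src$device_complaints + 1))
    expect_equal(row$device_count, src$device_count)
  }
})
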