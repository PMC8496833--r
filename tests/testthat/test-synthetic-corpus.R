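test_that("config validation rejects infeasible or malformed settings", {
  expect_error(generator_config(predicate_count_pmf = c("1" = 0.5, "2" = 0.4)),
               "sum 1")
  expect_error(generator_config(predicate_count_pmf = c("0" = 0.5, "2" = 0.5)),
               "integers >= 1")
  expect_error(generator_config(n_roots = 0), "n_roots")
  expect_error(generator_config(n_devices = 5, n_roots = 12), "n_devices")
  expect_error(generator_config(year_min = 2020, year_max = 1997), "year_min")
  expect_error(generator_config(mutation_rate_range = c(0.5, 0.1)),
               "mutation_rate_range")
  expect_error(generator_config(n_roots = 12, n_procodes = 20), "founder")
  # non-root devices but no room to order an edge in time
  expect_error(generator_config(n_devices = 20, n_roots = 12,
                                year_min = 2000, year_max = 2000),
               "infeasible")
})

test_that("a single root device yields one summary and no edges", {
  cfg <- generator_config(n_devices = 1L, n_roots = 1L, n_procodes = 1L,
                          n_recalled = 0L, n_outlier_procodes = 0L,
                          seed = 3L)
  corp <- generate_corpus(cfg)
  expect_equal(nrow(corp$metadata), 1)
  expect_equal(nrow(corp$ground_truth$true_edges), 0)
  expect_length(corp$summaries, 1)
  expect_match(names(corp$summaries), "^DEN[0-9]{6}$")
})

test_that("generation is a pure function of config and seed", {
  cfg <- generator_config(n_devices = 60L, n_roots = 4L, n_procodes = 4L,
                          n_recalled = 2L, seed = 9L)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$summaries, b$summaries)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$surveillance, b$surveillance)
  expect_identical(a$ground_truth, b$ground_truth)
  # and byte-identical on disk
  d1 <- tempfile(); d2 <- tempfile()
  write_corpus(a, d1); write_corpus(b, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("edges point strictly backward in year with no self-edges", {
  corp <- small_corpus()
  te <- corp$ground_truth$true_edges
  yr <- setNames(corp$metadata$decision_year, corp$metadata$device_id)
  expect_true(all(te$descendant_id %in% corp$metadata$device_id))
  expect_true(all(te$predicate_id %in% corp$metadata$device_id))
  expect_true(all(yr[te$descendant_id] > yr[te$predicate_id]))
  expect_false(any(te$descendant_id == te$predicate_id))
})

test_that("zero mutation copies predicate text verbatim (bow cosine 1)", {
  cfg <- generator_config(n_devices = 30L, n_roots = 3L, n_procodes = 3L,
                          n_recalled = 0L, n_outlier_procodes = 0L,
                          mutation_rate_range = c(0, 0), seed = 5L)
  corp <- generate_corpus(cfg)
  d <- tempfile(); write_corpus(corp, d)
  docs <- parse_corpus_dir(file.path(d, "summaries"))
  te <- corp$ground_truth$true_edges
  primary <- te[!is.na(te$mutation_rate), ]
  for (i in seq_len(nrow(primary))) {
    a <- docs[[primary$descendant_id[i]]]
    b <- docs[[primary$predicate_id[i]]]
    expect_identical(a$sections, b$sections)
    s <- device_similarity(a, b, "bow")
    expect_equal(unname(s$scores["combined"]), 1)
  }
})

test_that("planted outlier codes have the largest complaint-to-device ratios", {
  cfg <- generator_config(n_devices = 200L, n_roots = 10L, n_procodes = 10L,
                          n_outlier_procodes = 2L, n_recalled = 4L, seed = 7L)
  corp <- generate_corpus(cfg)
  surv <- corp$surveillance
  ratio <- surv$device_complaints / surv$device_count
  top2 <- surv$product_code[order(-ratio)][1:2]
  expect_setequal(top2, corp$ground_truth$outlier_procodes)
  expect_gt(min(ratio[surv$product_code %in% top2]),
            max(ratio[!surv$product_code %in% top2]))
})

test_that("rendered summaries round-trip through the parser", {
  secs <- toy_sections()
  txt <- render_summary_text("K000002", secs, c("K000001"))
  doc <- parse_summary(txt, "K000002")
  expect_equal(doc$predicates, "K000001")
  expect_identical(doc$sections[names(secs)], secs)
  expect_equal(doc$parse_status, "ok")

  txt0 <- render_summary_text("K000002", secs, character())
  expect_length(parse_summary(txt0, "K000002")$predicates, 0)

  txtd <- render_summary_text("DEN000001", secs, character())
  expect_equal(extract_device_ids(txtd), "DEN000001")
  expect_length(parse_summary(txtd, "DEN000001")$predicates, 0)

  expect_error(render_summary_text("X123", secs), "malformed")
  expect_error(render_summary_text("K000002", secs, "KABCDEF"), "malformed")
})

test_that("mean edge similarity is non-increasing across mutation-rate bins", {
  cfg <- generator_config(n_devices = 320L, n_roots = 4L, n_procodes = 4L,
                          n_recalled = 2L,
                          mutation_rate_range = c(0, 0.9), seed = 12L)
  corp <- generate_corpus(cfg)
  d <- tempfile(); write_corpus(corp, d)
  docs <- parse_corpus_dir(file.path(d, "summaries"))
  te <- corp$ground_truth$true_edges
  primary <- te[!is.na(te$mutation_rate), ]
  sim <- vapply(seq_len(nrow(primary)), function(i) {
    s <- device_similarity(docs[[primary$descendant_id[i]]],
                           docs[[primary$predicate_id[i]]], "bow")
    unname(s$scores["combined"])
  }, numeric(1))
  bins <- cut(primary$mutation_rate, breaks = seq(0, 0.9, by = 0.18),
              include.lowest = TRUE)
  expect_true(all(table(bins) >= 50))
  means <- tapply(sim, bins, mean)
  expect_true(all(diff(means) < 0))
})

test_that("ocr noise flag corrupts summaries into the unreadable path", {
  cfg <- generator_config(n_devices = 40L, n_roots = 4L, n_procodes = 4L,
                          n_recalled = 2L, ocr_noise_frac = 0.25, seed = 8L)
  corp <- generate_corpus(cfg)
  d <- tempfile(); write_corpus(corp, d)
  docs <- parse_corpus_dir(file.path(d, "summaries"))
  status <- vapply(docs, `[[`, character(1), "parse_status")
  expect_equal(sum(status == "unreadable"), 10)
  expect_equal(sum(status == "ok"), 30)
})
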