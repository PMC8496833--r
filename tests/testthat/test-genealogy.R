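table1_graph <- function() graph_from_edges(mrn_lineage())

test_that("the published nitric-oxide lineage rebuilds exactly", {
  lin <- mrn_lineage()
  g <- table1_graph()
  expect_equal(nrow(g$edges), 18)
  expect_equal(descendant_count(g, "K061901"), 11)
  expect_equal(branching_factor(g, "K974562"), 0)
  expect_equal(branching_factor(g, "DEN000001"), 1)
  # hand-traversal of the printed chain K143213 -> ... -> K974562
  expect_equal(ancestral_closure(g, "K143213"),
               sort(c("K143213", "K131686", "K130605", "K121021",
                      "K061901", "K974562")))
  sub <- traverse_from(g, "K974562")
  expect_setequal(unique(c(sub$predicate_id, sub$descendant_id)),
                  unique(c(lin$predicate_id, lin$descendant_id)))
  expect_equal(nrow(sub), 18)
})

test_that("graph construction recovers planted edges and flags anomalies", {
  corp <- small_corpus()
  g <- small_graph()
  expect_setequal(edge_keys(g$edges), edge_keys(corp$ground_truth$true_edges))
  # duplicate metadata IDs are fatal
  md2 <- rbind(corp$metadata, corp$metadata[1, ])
  expect_error(build_graph(md2, small_docs()), "duplicate")
  # self-loops dropped with a warning
  parsed <- list(list(device_id = "K000001", predicates = c("K000001", "K000002")))
  md <- data.frame(device_id = "K000001", decision_year = 2000,
                   product_code = "AAA", summary_available = 1L)
  expect_warning(g2 <- build_graph(md, parsed), "self-citation")
  expect_equal(nrow(g2$edges), 1)
  # cited-but-unknown predicate becomes a stub node
  stub <- g2$nodes[g2$nodes$device_id == "K000002", ]
  expect_equal(stub$summary_available, 0L)
  expect_true(is.na(stub$decision_year))
})

test_that("degree and closure statistics match igraph on synthetic data", {
  skip_if_not_installed("igraph")
  g <- small_graph()
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("descendant_id", "predicate_id")], directed = TRUE,
    vertices = g$nodes$device_id)
  ids <- sample(g$nodes$device_id, 25)
  for (id in ids) {
    expect_equal(branching_factor(g, id),
                 unname(igraph::degree(ig, id, mode = "out")))
    expect_equal(descendant_count(g, id),
                 unname(igraph::degree(ig, id, mode = "in")))
    expect_setequal(ancestral_closure(g, id),
                    names(igraph::subcomponent(ig, id, mode = "out")))
    sub <- traverse_from(g, id)
    reach <- names(igraph::subcomponent(ig, id, mode = "in"))
    expect_setequal(unique(c(sub$predicate_id, sub$descendant_id, id)),
                    unique(c(reach, id)))
  }
  expect_error(branching_factor(g, "K999999"), "unknown")
  expect_error(descendant_count(g, "K999999"), "unknown")
  expect_error(traverse_from(g, "K999999"), "unknown")
})

test_that("closure is monotone and idempotent; degrees sum to edge count", {
  g <- small_graph()
  set.seed(1)
  small <- sample(g$nodes$device_id, 5)
  big <- c(small, sample(setdiff(g$nodes$device_id, small), 10))
  c_small <- ancestral_closure(g, small)
  c_big <- ancestral_closure(g, big)
  expect_true(all(c_small %in% c_big))
  expect_equal(ancestral_closure(g, c_small), c_small)
  bf <- vapply(g$nodes$device_id, function(id) branching_factor(g, id), 1L)
  expect_equal(sum(bf), nrow(g$edges))
})

test_that("branching histogram partitions the ancestral closure by year", {
  g <- small_graph()
  cohort <- g$nodes$device_id[g$nodes$decision_year ==
                                max(g$nodes$decision_year)]
  h <- branching_histogram(g, cohort)
  members <- ancestral_closure(g, cohort)
  expect_equal(sum(h$count), length(members))
  # brute-force recomputation
  bf <- vapply(members, function(id) branching_factor(g, id), 1L)
  yr <- g$nodes$decision_year[match(members, g$nodes$device_id)]
  for (i in seq_len(nrow(h))) {
    expect_equal(h$count[i],
                 sum(bf == h$branching_factor[i] & yr == h$year[i]))
  }
  # cohort of roots only: all mass at branching factor 0
  roots <- g$nodes$device_id[grepl("^DEN", g$nodes$device_id)]
  h0 <- branching_histogram(g, roots)
  expect_true(all(h0$branching_factor == 0))
  # an extreme fan-in device keeps its full out-degree
  wide <- data.frame(descendant_id = "K200001",
                     predicate_id = sprintf("K1%05d", 1:62))
  expect_equal(branching_factor(graph_from_edges(wide), "K200001"), 62)
})

test_that("cycles are detected and traversal refuses to revisit nodes", {
  g <- small_graph()
  expect_length(detect_cycles(g), 0)
  cyc <- graph_from_edges(data.frame(
    descendant_id = c("K000001", "K000002", "K000003"),
    predicate_id = c("K000002", "K000001", "K000001")))
  found <- detect_cycles(cyc)
  expect_length(found, 1)
  expect_setequal(found[[1]], c("K000001", "K000002"))
  # traversal terminates despite the cycle
  sub <- traverse_from(cyc, "K000001")
  expect_true(nrow(sub) >= 2)
})

test_that("sankey export carries scores and flags unscored links", {
  lin <- mrn_lineage()
  g <- table1_graph()
  sub <- traverse_from(g, "K974562")
  scores <- data.frame(predicate_id = lin$predicate_id,
                       descendant_id = lin$descendant_id,
                       value = lin$similarity)
  sk <- export_sankey(sub, scores)
  expect_length(sk$links, 18)
  expect_length(sk$nodes, 19)
  val <- vapply(sk$links, `[[`, numeric(1), "value")
  scored <- vapply(sk$links, `[[`, logical(1), "scored")
  key <- vapply(sk$links, function(l) paste(l$source, l$target), "")
  want <- setNames(lin$similarity, paste(lin$predicate_id, lin$descendant_id))
  expect_equal(val[scored], unname(want[key[scored]]))
  # the three N/A rows (summaries not public) are flagged, weight 0
  expect_equal(sum(!scored), 3)
  expect_true(all(val[!scored] == 0))
  expect_equal(export_sankey(sub[0, ], scores), list(nodes = list(),
                                                     links = list()))
})
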