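# Shared fixtures: generated synthetic corpora, cached per test run.

.fixture_env <- new.env(parent = emptyenv())

# A modest corpus used by most tests (fast to generate and parse).
small_corpus <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- generator_config(n_devices = 120L, n_roots = 6L, n_procodes = 6L,
                            n_recalled = 4L, seed = 42L)
    .fixture_env$small <- generate_corpus(cfg)
  }
  .fixture_env$small
}

# Parsed documents for the small corpus (written to disk and re-read, so
# parsing exercises the real file round-trip).
small_docs <- function() {
  if (is.null(.fixture_env$small_docs)) {
    d <- tempfile("corpus")
    write_corpus(small_corpus(), d)
    .fixture_env$small_dir <- d
    .fixture_env$small_docs <- parse_corpus_dir(file.path(d, "summaries"))
  }
  .fixture_env$small_docs
}

small_dir <- function() {
  small_docs()
  .fixture_env$small_dir
}

small_graph <- function() {
  if (is.null(.fixture_env$small_graph)) {
    .fixture_env$small_graph <- build_graph(small_corpus()$metadata,
                                            small_docs())
  }
  .fixture_env$small_graph
}

# Edge keys for set comparisons.
edge_keys <- function(df, from = "descendant_id", to = "predicate_id") {
  paste(df[[from]], df[[to]], sep = "->")
}

# A tiny hand-buildable section pair for parser tests.
toy_sections <- function() {
  list(indications_for_use = "Continuous subcutaneous delivery of insulin.",
       device_description = "A portable pump with a reservoir and cannula.")
}
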