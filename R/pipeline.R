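# End-to-end orchestration: ingest -> graph -> similarity -> year
# summaries -> traversal -> surveillance, with file-based stage hand-off
# and a machine-readable run report.

#' Pipeline configuration
#'
#' Collects every input path, tunable and threshold for a full analysis
#' run. All stage hand-offs are files (JSON-lines/CSV) so each stage is
#' independently inspectable and re-runnable.
#'
#' @param summaries_dir Directory of `<device_id>.txt` summary files.
#' @param metadata_csv Device metadata CSV (`device_id`, `decision_year`,
#'   `product_code`, `summary_available`).
#' @param surveillance_csv Product-code surveillance CSV; `NULL` skips the
#'   surveillance stage.
#' @param output_dir Directory for all emitted artifacts.
#' @param method Similarity method, `"bow"` or `"embedding"`.
#' @param dimension Embedding dimension (used when `method = "embedding"`).
#' @param seed Seed for embedding training.
#' @param roots Device IDs to traverse forward from; default every
#'   `DEN`-prefixed device in the metadata.
#' @param year_range Optional `c(from, to)` filter for the per-year
#'   equivalence summaries.
#' @param recall_threshold Mean-similarity threshold for the
#'   recalled-vs-marketed comparison.
#' @param outlier_k Number of outlier product codes to flag.
#' @param recalled_ids Optional device IDs with Class-1 recalls; when
#'   non-empty the recalled-vs-marketed comparison runs against
#'   `marketed_ids` (default: all other devices).
#' @param marketed_ids Optional comparison set for the recall analysis.
#' @param stopwords_path Optional stop-word file (default bundled list).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(summaries_dir, metadata_csv,
                            surveillance_csv = NULL, output_dir,
                            method = c("bow", "embedding"),
                            dimension = 500L, seed = 1L, roots = NULL,
                            year_range = NULL, recall_threshold = 0.5,
                            outlier_k = 7L, recalled_ids = character(),
                            marketed_ids = NULL, stopwords_path = NULL) {
  method <- match.arg(method)
  stopifnot(dimension > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes ingest, graph construction, edge similarity scoring, per-year
#' equivalence summaries, forward traversals from the requested roots
#' (with Sankey JSON export), and — when a surveillance table is supplied —
#' outlier identification, the scatter table and optionally the
#' recalled-vs-marketed comparison. Every artifact is written under
#' `output_dir` and listed in the run report
#' (`run_report.json`), together with stage counts (devices parsed, edges,
#' unscorable edges, rejected surveillance rows) and the config echo, so a
#' run is reproducible from the report alone. Any stage failure halts the
#' run with a stage-named error.
#'
#' @param config A [pipeline_config()].
#' @return The run report, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  artifacts <- character(0)
  report <- list(package_version = as.character(utils::packageVersion("predigree")),
                 config = config[!vapply(config, is.null, logical(1))],
                 counts = list())

  # -- ingest ---------------------------------------------------------
  stop_words <- if (is.null(config$stopwords_path)) default_stopwords() else
    default_stopwords(config$stopwords_path)
  docs <- tryCatch(parse_corpus_dir(config$summaries_dir, stop_words),
                   error = function(e) stop("ingest: ", conditionMessage(e),
                                            call. = FALSE))
  write_parsed_jsonl(docs, out("parsed.jsonl"))
  artifacts <- c(artifacts, out("parsed.jsonl"))
  status <- vapply(docs, `[[`, character(1), "parse_status")
  report$counts$devices_parsed <- length(docs)
  report$counts$parse_ok <- sum(status == "ok")
  report$counts$parse_failed <- sum(status != "ok")

  # -- graph ----------------------------------------------------------
  metadata <- read.csv(config$metadata_csv, stringsAsFactors = FALSE)
  graph <- tryCatch(build_graph(metadata, docs),
                    error = function(e) stop("graph: ", conditionMessage(e),
                                             call. = FALSE))
  write_edges_csv(graph, out("edges.csv"))
  artifacts <- c(artifacts, out("edges.csv"))
  report$counts$edges <- nrow(graph$edges)
  report$counts$cycles <- length(detect_cycles(graph))

  # -- similarity -----------------------------------------------------
  model <- NULL
  if (config$method == "embedding") {
    streams <- unlist(lapply(docs[status == "ok"], `[[`, "tokens"),
                      recursive = FALSE)
    model <- train_embeddings(streams, dimension = config$dimension,
                              seed = config$seed)
    save_embeddings(model, out("embeddings.txt"))
    artifacts <- c(artifacts, out("embeddings.txt"))
  }
  scores <- score_edges(graph, docs, config$method, model)
  write.csv(scores, out("edge_scores.csv"), row.names = FALSE)
  artifacts <- c(artifacts, out("edge_scores.csv"))
  report$counts$unscorable_edges <-
    sum(scores$scorable[scores$section == "combined"] == 0L)

  # -- per-year equivalence ------------------------------------------
  years <- equivalence_by_year(graph, scores, config$year_range)
  write.csv(years, out("equivalence_by_year.csv"), row.names = FALSE)
  artifacts <- c(artifacts, out("equivalence_by_year.csv"))
  report$counts$years_summarised <- nrow(years)
  report$counts$devices_excluded_from_years <- sum(years$n_excluded)

  # -- traversal ------------------------------------------------------
  roots <- config$roots
  if (is.null(roots)) {
    roots <- grep("^DEN", graph$nodes$device_id, value = TRUE)
  }
  comb <- scores[scores$section == "combined" & scores$scorable == 1L, ]
  link_scores <- data.frame(predicate_id = comb$id_b,
                            descendant_id = comb$id_a,
                            value = comb$value, stringsAsFactors = FALSE)
  for (root in roots) {
    subtree <- traverse_from(graph, root)
    sankey <- export_sankey(subtree, link_scores)
    path <- out(paste0("sankey_", root, ".json"))
    jsonlite::write_json(sankey, path, auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, path)
  }
  report$counts$roots_traversed <- length(roots)

  # -- surveillance ---------------------------------------------------
  if (!is.null(config$surveillance_csv)) {
    stats <- tryCatch(load_surveillance(config$surveillance_csv),
                      error = function(e) stop("surveillance: ",
                                               conditionMessage(e),
                                               call. = FALSE))
    report$counts$surveillance_rows_rejected <- length(attr(stats, "rejected"))
    outliers <- identify_outliers(stats, k = min(config$outlier_k, nrow(stats)))
    writeLines(outliers, out("outlier_procodes.txt"))
    write.csv(scatter_table(stats), out("scatter_table.csv"),
              row.names = FALSE)
    artifacts <- c(artifacts, out("outlier_procodes.txt"),
                   out("scatter_table.csv"))
    report$counts$outlier_procodes <- length(outliers)
    if (length(config$recalled_ids)) {
      marketed <- config$marketed_ids
      if (is.null(marketed)) {
        marketed <- setdiff(names(docs), config$recalled_ids)
      }
      cmp <- recalled_vs_marketed(config$recalled_ids, marketed, docs,
                                  config$method, model,
                                  config$recall_threshold)
      recall_report <- list(
        per_recalled_mean = as.list(cmp$per_recalled_mean),
        overall_mean = cmp$overall_mean,
        below_threshold = cmp$below_threshold,
        threshold = cmp$threshold,
        n_excluded = cmp$n_excluded)
      jsonlite::write_json(recall_report, out("recalled_vs_marketed.json"),
                           auto_unbox = TRUE, digits = NA)
      artifacts <- c(artifacts, out("recalled_vs_marketed.json"))
    }
  }

  report$artifacts <- artifacts
  jsonlite::write_json(report, out("run_report.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(report)
}
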