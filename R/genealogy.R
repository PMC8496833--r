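# Directed predicate genealogy: descendant -> predicate edges over device
# IDs, branching statistics, ancestral closures, forward traversal and
# Sankey-ready export.

#' Build the predicate genealogy graph
#'
#' One directed edge per (device, cited predicate), oriented descendant ->
#' predicate, so a device's branching factor is its out-degree. Cited
#' predicates absent from the metadata become stub nodes (unknown year,
#' `summary_available = 0`). Self-citations are dropped with a warning;
#' duplicate device IDs in the metadata are a hard failure.
#'
#' @param metadata Data frame with columns `device_id`, `decision_year`,
#'   `product_code`, `summary_available`.
#' @param parsed Named list of parsed records (each with `device_id` and
#'   `predicates`), e.g. from [parse_corpus_dir()].
#' @return Object of class `genealogy_graph`: list with `nodes` (metadata
#'   data.frame including stubs) and `edges` (data.frame `descendant_id`,
#'   `predicate_id`, `descendant_year`).
#' @export
build_graph <- function(metadata, parsed) {
  if (anyDuplicated(metadata$device_id)) {
    stop("duplicate device IDs in metadata: ",
         paste(unique(metadata$device_id[duplicated(metadata$device_id)]),
               collapse = ", "))
  }
  el <- lapply(parsed, function(d) {
    preds <- unique(d$predicates)
    if (length(preds) == 0) return(NULL)
    data.frame(descendant_id = d$device_id, predicate_id = preds,
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, el)
  if (is.null(edges)) {
    edges <- data.frame(descendant_id = character(),
                        predicate_id = character(), stringsAsFactors = FALSE)
  }
  self <- edges$descendant_id == edges$predicate_id
  if (any(self)) {
    warning("dropping ", sum(self), " self-citation edge(s): ",
            paste(unique(edges$descendant_id[self]), collapse = ", "))
    edges <- edges[!self, , drop = FALSE]
  }
  edges <- unique(edges)
  year_of <- setNames(metadata$decision_year, metadata$device_id)
  edges$descendant_year <- unname(year_of[edges$descendant_id])
  rownames(edges) <- NULL

  all_ids <- unique(c(metadata$device_id,
                      vapply(parsed, `[[`, character(1), "device_id"),
                      edges$predicate_id))
  stubs <- setdiff(all_ids, metadata$device_id)
  nodes <- metadata[, c("device_id", "decision_year", "product_code",
                        "summary_available")]
  if (length(stubs)) {
    nodes <- rbind(nodes, data.frame(
      device_id = stubs, decision_year = NA_integer_,
      product_code = NA_character_, summary_available = 0L,
      stringsAsFactors = FALSE))
  }
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "genealogy_graph")
}

#' Build a graph directly from an edge list
#'
#' Convenience constructor for printed or externally supplied edge lists
#' (e.g. a published lineage table): endpoints become nodes with unknown
#' metadata.
#'
#' @param edges Data frame with columns `descendant_id`, `predicate_id`.
#' @param metadata Optional metadata for (a subset of) the endpoints.
#' @return A `genealogy_graph`.
#' @export
graph_from_edges <- function(edges, metadata = NULL) {
  ids <- unique(c(edges$descendant_id, edges$predicate_id))
  if (is.null(metadata)) {
    metadata <- data.frame(device_id = character(), decision_year = integer(),
                           product_code = character(),
                           summary_available = integer(),
                           stringsAsFactors = FALSE)
  }
  parsed <- lapply(ids, function(id) {
    list(device_id = id,
         predicates = edges$predicate_id[edges$descendant_id == id])
  })
  names(parsed) <- ids
  build_graph(metadata, parsed)
}

check_node <- function(graph, device_id) {
  if (!device_id %in% graph$nodes$device_id) {
    stop("unknown device: ", device_id)
  }
}

#' Branching factor (number of predicates cited)
#'
#' The out-degree of a device in the descendant -> predicate graph: how
#' many predicates it cites. Root/De Novo devices have branching factor 0.
#'
#' @param graph A `genealogy_graph`.
#' @param device_id Device ID present in the graph.
#' @return Integer count.
#' @export
branching_factor <- function(graph, device_id) {
  check_node(graph, device_id)
  sum(graph$edges$descendant_id == device_id)
}

#' Number of direct descendants
#'
#' The in-degree: how many devices cite this device as a predicate.
#'
#' @inheritParams branching_factor
#' @return Integer count.
#' @export
descendant_count <- function(graph, device_id) {
  check_node(graph, device_id)
  sum(graph$edges$predicate_id == device_id)
}

#' Ancestral closure of a device cohort
#'
#' All devices reachable from the cohort by repeatedly following
#' descendant -> predicate edges, cohort included (the fixed point of
#' predicate expansion). Stub nodes terminate expansion when they cite
#' nothing.
#'
#' @param graph A `genealogy_graph`.
#' @param cohort_ids Character vector of device IDs in the graph.
#' @return Character vector of device IDs (sorted).
#' @export
ancestral_closure <- function(graph, cohort_ids) {
  for (id in cohort_ids) check_node(graph, id)
  preds_of <- split(graph$edges$predicate_id, graph$edges$descendant_id)
  seen <- unique(cohort_ids)
  frontier <- seen
  while (length(frontier)) {
    nxt <- unique(unlist(preds_of[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  sort(seen)
}

#' Branching-factor histogram over an ancestral tree
#'
#' Expands the cohort to its ancestral closure and tabulates branching
#' factors by year. A device is attributed to its own decision year
#' (unknown years are grouped under `NA`); the cohort used and the year
#' attribution are explicit parameters because published per-year
#' histograms are sensitive to both choices.
#'
#' @param graph A `genealogy_graph`.
#' @param cohort_ids Cohort whose ancestral tree is histogrammed.
#' @return Data frame `year`, `branching_factor`, `count`; counts per year
#'   sum to the number of closure members attributed to that year.
#' @export
branching_histogram <- function(graph, cohort_ids) {
  members <- ancestral_closure(graph, cohort_ids)
  bf <- vapply(members, function(id) branching_factor(graph, id), integer(1))
  yr <- graph$nodes$decision_year[match(members, graph$nodes$device_id)]
  tab <- as.data.frame(table(year = yr, branching_factor = bf, useNA = "ifany"),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, ]
  out <- data.frame(year = suppressWarnings(as.integer(as.character(tab$year))),
                    branching_factor = as.integer(as.character(tab$branching_factor)),
                    count = tab$Freq)
  out <- out[order(out$year, out$branching_factor), ]
  rownames(out) <- NULL
  out
}

#' Detect citation cycles
#'
#' Predicate citations should point strictly backwards in time, so the
#' genealogy should be acyclic; scraped real-world data can contain
#' citation errors that create cycles. Traversals refuse to revisit nodes,
#' so cycles are reported rather than fatal.
#'
#' @param graph A `genealogy_graph`.
#' @return List of cycles, each a character vector of device IDs in cycle
#'   order; empty list when the graph is a DAG.
#' @export
detect_cycles <- function(graph) {
  adj <- split(graph$edges$predicate_id, graph$edges$descendant_id)
  color <- new.env(parent = emptyenv())
  stack <- character(0)
  cycles <- list()
  visit <- function(u) {
    assign(u, 1L, envir = color)           # on stack
    stack <<- c(stack, u)
    for (v in adj[[u]]) {
      st <- if (exists(v, envir = color, inherits = FALSE))
        get(v, envir = color) else 0L
      if (st == 0L) visit(v)
      else if (st == 1L) {
        at <- match(v, stack)
        cycles[[length(cycles) + 1]] <<- stack[at:length(stack)]
      }
    }
    assign(u, 2L, envir = color)           # done
    stack <<- stack[-length(stack)]
  }
  for (u in graph$nodes$device_id) {
    st <- if (exists(u, envir = color, inherits = FALSE))
      get(u, envir = color) else 0L
    if (st == 0L) visit(u)
  }
  cycles
}

#' Forward traversal from a root device
#'
#' All edges on paths from the root forward to its descendants (reverse
#' reachability in the descendant -> predicate graph), reported in
#' predicate -> descendant orientation and ordered by descendant then
#' predicate ID. Cycles, if present, are broken by never revisiting a
#' node.
#'
#' @param graph A `genealogy_graph`.
#' @param root_id Device ID to traverse from (typically a De Novo founder).
#' @return Data frame `predicate_id`, `descendant_id`; zero rows for a
#'   device with no descendants.
#' @export
traverse_from <- function(graph, root_id) {
  check_node(graph, root_id)
  desc_of <- split(graph$edges$descendant_id, graph$edges$predicate_id)
  seen <- root_id
  frontier <- root_id
  out <- list()
  while (length(frontier)) {
    step <- graph$edges[graph$edges$predicate_id %in% frontier, , drop = FALSE]
    if (nrow(step)) {
      out[[length(out) + 1]] <- data.frame(predicate_id = step$predicate_id,
                                           descendant_id = step$descendant_id,
                                           stringsAsFactors = FALSE)
    }
    frontier <- setdiff(unique(step$descendant_id), seen)
    seen <- c(seen, frontier)
  }
  edges <- if (length(out)) unique(do.call(rbind, out)) else
    data.frame(predicate_id = character(), descendant_id = character(),
               stringsAsFactors = FALSE)
  edges <- edges[order(edges$descendant_id, edges$predicate_id), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Export a traversal subtree as a Sankey node/link structure
#'
#' Links carry the similarity score of the corresponding predicate ->
#' descendant pair as their weight; links touching devices without a
#' scorable summary get `default_weight` and `scored = FALSE` so renderers
#' can style them distinctly (published genealogy diagrams show such links
#' as exceptions).
#'
#' @param subtree Data frame `predicate_id`, `descendant_id` from
#'   [traverse_from()].
#' @param scores Data frame `predicate_id`, `descendant_id`, `value` giving
#'   similarity scores for (a subset of) the links; `NA` values are treated
#'   as unscored.
#' @param default_weight Weight assigned to unscored links.
#' @return List `nodes` (list of `list(id = ...)`) and `links` (list of
#'   `list(source, target, value, scored)`), JSON-ready.
#' @export
export_sankey <- function(subtree, scores = NULL, default_weight = 0) {
  if (nrow(subtree) == 0) return(list(nodes = list(), links = list()))
  ids <- unique(c(subtree$predicate_id, subtree$descendant_id))
  key <- function(p, d) paste(p, d, sep = "->")
  score_map <- if (!is.null(scores) && nrow(scores)) {
    setNames(scores$value, key(scores$predicate_id, scores$descendant_id))
  } else setNames(numeric(0), character(0))
  links <- lapply(seq_len(nrow(subtree)), function(i) {
    k <- key(subtree$predicate_id[i], subtree$descendant_id[i])
    v <- score_map[[k]]
    scored <- !is.null(v) && !is.na(v)
    list(source = subtree$predicate_id[i],
         target = subtree$descendant_id[i],
         value = if (scored) unname(v) else default_weight,
         scored = scored)
  })
  list(nodes = lapply(ids, function(id) list(id = id)), links = links)
}

#' Write graph edges as CSV
#'
#' @param graph A `genealogy_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges_csv <- function(graph, path) {
  write.csv(graph$edges, path, row.names = FALSE)
  invisible(path)
}

#' Published De Novo lineage fixture (nitric-oxide delivery devices)
#'
#' The printed predicate -> descendant lineage for FDA product code MRN
#' (nitric oxide administration apparatus): 18 edges rooted at K974562,
#' which was reclassified as De Novo device DEN000001, with the published
#' pairwise similarity score where available (`NA` for devices whose
#' summary statements are not public).
#'
#' @return Data frame `predicate_id`, `descendant_id`, `similarity`.
#' @export
mrn_lineage <- function() {
  path <- system.file("extdata", "mrn_lineage.csv", package = "predigree")
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c("character", "character", "numeric"))
}
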