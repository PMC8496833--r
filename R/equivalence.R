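# Substantial-equivalence scoring: bag-of-words and embedding document
# vectors, cosine similarity, per-edge scores and per-year summaries.

#' Bag-of-words vector
#'
#' Counts each distinct token; the naive embedding of word frequencies in
#' which an n-word vocabulary spans an n-dimensional space.
#'
#' @param tokens Character vector of cleaned tokens.
#' @return Named numeric vector of counts (no zero entries; empty input
#'   gives an empty vector).
#' @export
bow_vector <- function(tokens) {
  if (length(tokens) == 0) return(setNames(numeric(0), character(0)))
  tab <- table(tokens)
  setNames(as.numeric(tab), names(tab))
}

#' Cosine similarity between two document vectors
#'
#' The cosine of the angle between two vectors: their dot product divided
#' by the product of their Euclidean norms. Named (sparse bag-of-words)
#' vectors are aligned on the union of their terms; dense vectors must
#' share a dimension. A zero-norm operand (empty section, all
#' out-of-vocabulary tokens) yields 0 with attribute `zero_norm = TRUE`
#' rather than an error.
#'
#' @param a,b Numeric vectors; both named (sparse) or both dense of equal
#'   length.
#' @return Similarity in \[-1, 1\] (in \[0, 1\] for count vectors).
#' @export
cosine <- function(a, b) {
  named <- !is.null(names(a)) || !is.null(names(b))
  if (named) {
    if (is.null(names(a)) || is.null(names(b))) {
      stop("cannot mix named (sparse) and unnamed (dense) vectors")
    }
    terms <- union(names(a), names(b))
    av <- setNames(numeric(length(terms)), terms)
    bv <- av
    av[names(a)] <- a
    bv[names(b)] <- b
    a <- av; b <- bv
  } else if (length(a) != length(b)) {
    stop("dense vectors of mismatched dimension: ",
         length(a), " vs ", length(b))
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    return(structure(0, zero_norm = TRUE))
  }
  v <- sum(a * b) / (na * nb)
  stopifnot(is.finite(v))
  v
}

#' Aggregate token vectors into a document vector
#'
#' Unweighted mean of the embedding vectors of all in-vocabulary tokens.
#' A document with no in-vocabulary token maps to the zero vector, flagged
#' with attribute `oov = TRUE` (a known limitation of corpus-trained
#' embeddings: unseen jargon cannot be represented).
#'
#' @param model An `embedding_model` from [train_embeddings()].
#' @param tokens Character vector of cleaned tokens.
#' @return Numeric vector of length `model$dimension`.
#' @export
doc_vector <- function(model, tokens) {
  stopifnot(inherits(model, "embedding_model"))
  idx <- match(tokens, model$vocabulary)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) {
    return(structure(numeric(model$dimension), oov = TRUE))
  }
  colMeans(model$vectors[idx, , drop = FALSE])
}

section_labels <- c("indications_for_use", "device_description")

#' Similarity between two parsed device summaries
#'
#' Scores the indications-for-use and device-description sections
#' separately and combines them as the arithmetic mean, using either raw
#' bag-of-words counts or embedding document vectors. Pairs in which
#' either document failed to parse are explicitly unscorable, never a
#' number.
#'
#' @param doc_a,doc_b `summary_document` records with `parse_status` "ok".
#' @param method `"bow"` or `"embedding"`.
#' @param model Required `embedding_model` when `method = "embedding"`.
#' @return List of class `similarity_score`: `id_a`, `id_b`, `method`,
#'   `scorable`, and when scorable a named numeric `scores` over
#'   `indications_for_use`, `device_description`, `combined`.
#' @export
device_similarity <- function(doc_a, doc_b, method = c("bow", "embedding"),
                              model = NULL) {
  method <- match.arg(method)
  res <- list(id_a = doc_a$device_id, id_b = doc_b$device_id,
              method = method, scorable = FALSE, scores = NULL)
  class(res) <- "similarity_score"
  if (!identical(doc_a$parse_status, "ok") ||
      !identical(doc_b$parse_status, "ok")) {
    return(res)
  }
  if (method == "embedding" && is.null(model)) {
    stop("method = 'embedding' requires a trained model")
  }
  per <- vapply(section_labels, function(sec) {
    ta <- doc_a$tokens[[sec]]; tb <- doc_b$tokens[[sec]]
    if (method == "bow") {
      as.numeric(cosine(bow_vector(ta), bow_vector(tb)))
    } else {
      as.numeric(cosine(doc_vector(model, ta), doc_vector(model, tb)))
    }
  }, numeric(1))
  res$scorable <- TRUE
  res$scores <- c(per, combined = mean(per))
  res
}

#' Score every edge of a genealogy graph
#'
#' Computes the combined similarity for each descendant -> predicate edge
#' whose two endpoint summaries both parsed; other edges are marked
#' unscorable.
#'
#' @param graph A `genealogy_graph`.
#' @param docs Named list of `summary_document` records.
#' @param method,model Passed to [device_similarity()].
#' @return Data frame `id_a` (descendant), `id_b` (predicate), `section`,
#'   `method`, `value`, `scorable`; one row per edge and section (the two
#'   sections plus `combined`).
#' @export
score_edges <- function(graph, docs, method = c("bow", "embedding"),
                        model = NULL) {
  method <- match.arg(method)
  edges <- graph$edges
  rows <- lapply(seq_len(nrow(edges)), function(i) {
    a <- docs[[edges$descendant_id[i]]]
    b <- docs[[edges$predicate_id[i]]]
    base <- data.frame(id_a = edges$descendant_id[i],
                       id_b = edges$predicate_id[i],
                       section = c(section_labels, "combined"),
                       method = method, stringsAsFactors = FALSE)
    if (is.null(a) || is.null(b)) {
      base$value <- NA_real_; base$scorable <- 0L
      return(base)
    }
    s <- device_similarity(a, b, method, model)
    if (!s$scorable) {
      base$value <- NA_real_; base$scorable <- 0L
    } else {
      base$value <- unname(s$scores[base$section])
      base$scorable <- 1L
    }
    base
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id_a = character(), id_b = character(), section = character(),
               method = character(), value = numeric(), scorable = integer())
  rownames(out) <- NULL
  out
}

#' Per-year equivalence summaries
#'
#' For each device, averages the combined similarity to all its scorable
#' predicates; then summarises the per-device values by the device's
#' decision year (five-number summary plus mean). Years outside
#' `year_range` and devices with no scorable edge are excluded and
#' counted, mirroring the exclusion of years whose summaries cannot be
#' parsed.
#'
#' @param graph A `genealogy_graph`.
#' @param scores Edge score table from [score_edges()] (the `combined`
#'   rows are used).
#' @param year_range Optional `c(from, to)` filter on decision years.
#' @return Data frame `year`, `n`, `min`, `q1`, `median`, `q3`, `max`,
#'   `mean`, `n_excluded`; one row per year with at least one scorable
#'   device.
#' @export
equivalence_by_year <- function(graph, scores, year_range = NULL) {
  comb <- scores[scores$section == "combined", , drop = FALSE]
  yr <- setNames(graph$nodes$decision_year, graph$nodes$device_id)
  comb$year <- unname(yr[comb$id_a])
  if (!is.null(year_range)) {
    keep <- !is.na(comb$year) & comb$year >= year_range[1] &
      comb$year <= year_range[2]
    comb <- comb[keep, , drop = FALSE]
  }
  if (nrow(comb) == 0) {
    return(data.frame(year = integer(), n = integer(), min = numeric(),
                      q1 = numeric(), median = numeric(), q3 = numeric(),
                      max = numeric(), mean = numeric(),
                      n_excluded = integer()))
  }
  per_dev <- lapply(split(comb, comb$id_a), function(d) {
    ok <- d$scorable == 1L & !is.na(d$value)
    data.frame(device_id = d$id_a[1], year = d$year[1],
               value = if (any(ok)) mean(d$value[ok]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  per_dev <- do.call(rbind, per_dev)
  out <- lapply(split(per_dev, per_dev$year), function(d) {
    v <- d$value[!is.na(d$value)]
    n_exc <- sum(is.na(d$value))
    if (length(v) == 0) return(NULL)
    q <- unname(quantile(v, c(0, 0.25, 0.5, 0.75, 1)))
    data.frame(year = d$year[1], n = length(v), min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5], mean = mean(v),
               n_excluded = n_exc)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  out <- out[order(out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}
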