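# Training and persistence of the shallow word-embedding model.

#' Train word embeddings on a summary corpus
#'
#' Trains a two-layer continuous-bag-of-words network with negative
#' sampling on the token streams of the corpus, embedding each retained
#' vocabulary word into a `dimension`-dimensional space. Training is
#' single-threaded with a private RNG, so the vector table is a pure
#' function of the corpus, the hyperparameters and the seed.
#'
#' @param token_streams List of character vectors (one per document or
#'   section); at least one must be non-empty.
#' @param dimension Embedding dimension (default 500).
#' @param window Context window half-width.
#' @param epochs Passes over the corpus.
#' @param min_count Minimum corpus frequency for a word to be retained.
#' @param negative Negative samples per target word.
#' @param learning_rate Initial learning rate (decays linearly).
#' @param seed Integer seed for initialisation and sampling.
#' @return Object of class `embedding_model`: `vocabulary` (ordered by
#'   decreasing corpus frequency, ties alphabetical), `dimension`,
#'   `vectors` (|V| x dimension matrix, rows named by word), and
#'   `training_config`.
#' @export
train_embeddings <- function(token_streams, dimension = 500L, window = 5L,
                             epochs = 10L, min_count = 1L, negative = 5L,
                             learning_rate = 0.05, seed = 1L) {
  stopifnot(dimension >= 1, window >= 1, epochs >= 1, negative >= 0)
  token_streams <- token_streams[lengths(token_streams) > 0]
  if (length(token_streams) == 0) stop("empty corpus: no non-empty documents")
  counts <- table(unlist(token_streams, use.names = FALSE))
  counts <- counts[counts >= min_count]
  if (length(counts) == 0) stop("no vocabulary term reaches min_count")
  ord <- order(-as.integer(counts), names(counts))
  vocab <- names(counts)[ord]
  freq <- as.integer(counts)[ord]
  docs <- lapply(token_streams, function(toks) {
    idx <- match(toks, vocab)
    as.integer(idx[!is.na(idx)] - 1L)
  })
  docs <- docs[lengths(docs) > 0]
  if (length(docs) == 0) stop("empty corpus after vocabulary filtering")
  vecs <- .cbow_train(docs, freq, as.integer(dimension), as.integer(window),
                      as.integer(epochs), as.integer(negative),
                      learning_rate, as.integer(seed))
  rownames(vecs) <- vocab
  structure(list(vocabulary = vocab,
                 dimension = as.integer(dimension),
                 vectors = vecs,
                 training_config = list(algorithm = "cbow-negative-sampling",
                                        window = as.integer(window),
                                        epochs = as.integer(epochs),
                                        min_count = as.integer(min_count),
                                        negative = as.integer(negative),
                                        learning_rate = learning_rate,
                                        seed = as.integer(seed))),
            class = "embedding_model")
}

#' Save an embedding model as versioned plain text
#'
#' Line 1 is a version/shape header (`predigree-embedding 1 <V> <dim>`),
#' followed by one `word v1 ... vdim` line per vocabulary term, full
#' double precision.
#'
#' @param model An `embedding_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_embeddings <- function(model, path) {
  stopifnot(inherits(model, "embedding_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("predigree-embedding 1 %d %d",
                     length(model$vocabulary), model$dimension), con)
  for (i in seq_along(model$vocabulary)) {
    writeLines(paste(model$vocabulary[i],
                     paste(format(model$vectors[i, ], digits = 17,
                                  scientific = TRUE, trim = TRUE),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' Load an embedding model saved by [save_embeddings()]
#'
#' @param path Path to the text model file.
#' @return An `embedding_model` (training_config not preserved).
#' @export
load_embeddings <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1], " ")[[1]]
  if (length(header) != 4 || header[1] != "predigree-embedding") {
    stop("not a predigree embedding file: ", path)
  }
  v <- as.integer(header[3]); dim <- as.integer(header[4])
  stopifnot(length(lines) == v + 1)
  parts <- strsplit(lines[-1], " ", fixed = TRUE)
  vocab <- vapply(parts, `[[`, character(1), 1)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(dim)))
  rownames(vecs) <- vocab
  structure(list(vocabulary = vocab, dimension = dim, vectors = vecs,
                 training_config = NULL),
            class = "embedding_model")
}
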