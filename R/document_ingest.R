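# Parsing of raw 510(k) summary text: device-ID extraction, section
# segmentation, tokenisation and stop-word removal.

ID_PATTERN <- "(?:K|DEN)[0-9]{6}"

#' Default section heading synonyms
#'
#' Public 510(k) summaries vary in how they head the two scored sections;
#' the parser matches any synonym case-insensitively. The synonym sets are
#' configuration: extend them for corpora with other heading conventions.
#'
#' @return Named list mapping section label to a character vector of
#'   heading synonyms.
#' @export
default_headings <- function() {
  list(
    indications_for_use = c("indications for use", "intended use"),
    device_description  = c("device description", "description of the device")
  )
}

#' Default stop-word list
#'
#' Loads the bundled English stop-word list (one lowercase word per line).
#' Stop words are connective words ("a", "and", "but", ...) carrying no
#' device-specific content; they are removed before any similarity scoring.
#'
#' @param path Optional path to an alternative one-word-per-line file.
#' @return Character vector of lowercase stop words.
#' @export
default_stopwords <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stopwords.txt", package = "predigree")
  }
  words <- readLines(path, warn = FALSE)
  words <- tolower(trimws(words))
  words <- words[nzchar(words)]
  stopifnot(length(words) > 0)
  words
}

#' Extract 510(k)/De Novo device identifiers from text
#'
#' Finds every substring matching the device-ID grammar `K` followed by six
#' digits or `DEN` followed by six digits, case-insensitively, and returns
#' the unique IDs normalised to upper case in first-occurrence order.
#' PMA-style P-numbers are not matched.
#'
#' @param text Character scalar (any string; empty gives an empty result).
#' @return Character vector of unique upper-case device IDs.
#' @export
#' @examples
#' extract_device_ids("substantially equivalent to K974562 and DEN000001")
extract_device_ids <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(text)) return(character())
  m <- gregexpr(paste0("\\b", ID_PATTERN, "\\b"), text,
                ignore.case = TRUE, perl = TRUE)[[1]]
  if (m[1] == -1) return(character())
  ids <- toupper(regmatches(text, list(m))[[1]])
  unique(ids)
}

is_device_id <- function(x) grepl(paste0("^", ID_PATTERN, "$"), x)

# Fraction of characters outside letters, digits, whitespace and basic
# punctuation; proxies OCR garbage in scanned summaries.
garbage_fraction <- function(text) {
  n <- nchar(text)
  if (n == 0) return(0)
  clean <- gsub("[a-zA-Z0-9[:space:].,;:()'\"/?!%&+-]", "", text)
  nchar(clean) / n
}

#' Segment a summary into its two scored sections
#'
#' Locates the "Indications for Use" and "Device Description" headings
#' (case-insensitive, configurable synonym sets) and takes each section body
#' as the text from the end of its heading to the next recognised heading or
#' the end of the document. Documents whose character stream is mostly
#' garbage (as from failed OCR of old scanned PDFs) are flagged unreadable
#' and yield no sections.
#'
#' @param raw_text Character scalar, the full summary text.
#' @param headings Named list of heading synonym vectors
#'   (see [default_headings()]).
#' @param unreadable_threshold Maximum tolerated fraction of characters
#'   outside letters, digits, whitespace and basic punctuation.
#' @return List with `sections` (named list of trimmed body strings, possibly
#'   incomplete) and `parse_status` (one of `"ok"`, `"missing_section"`,
#'   `"unreadable"`).
#' @export
segment_sections <- function(raw_text, headings = default_headings(),
                             unreadable_threshold = 0.3) {
  stopifnot(is.character(raw_text), length(raw_text) == 1, nzchar(raw_text))
  if (garbage_fraction(raw_text) > unreadable_threshold) {
    return(list(sections = list(), parse_status = "unreadable"))
  }
  # first occurrence of any synonym per section label
  hits <- data.frame(label = character(), start = integer(), body_from = integer())
  for (label in names(headings)) {
    best <- NULL
    for (syn in headings[[label]]) {
      m <- regexpr(syn, raw_text, ignore.case = TRUE, fixed = FALSE)
      if (m[1] != -1 && (is.null(best) || m[1] < best[1])) {
        best <- c(m[1], m[1] + attr(m, "match.length"))
      }
    }
    if (!is.null(best)) {
      hits <- rbind(hits, data.frame(label = label, start = best[1],
                                     body_from = best[2]))
    }
  }
  if (nrow(hits) == 0) {
    return(list(sections = list(), parse_status = "missing_section"))
  }
  hits <- hits[order(hits$start), ]
  sections <- list()
  for (i in seq_len(nrow(hits))) {
    to <- if (i < nrow(hits)) hits$start[i + 1] - 1 else nchar(raw_text)
    body <- substr(raw_text, hits$body_from[i], to)
    body <- sub("^[[:space:]:]+", "", body)
    body <- sub("[[:space:]]+$", "", body)
    sections[[hits$label[i]]] <- body
  }
  complete <- all(names(headings) %in% names(sections)) &&
    all(nzchar(unlist(sections[names(headings)])))
  list(sections = sections,
       parse_status = if (complete) "ok" else "missing_section")
}

#' Tokenise a section body
#'
#' Lowercases, splits on runs of non-alphanumeric characters, and drops
#' stop words and single-character fragments. Device-ID-shaped tokens
#' (e.g. `k974562`) survive because they are alphanumeric.
#'
#' @param section_text Character scalar.
#' @param stop_words Character vector of lowercase stop words.
#' @return Character vector of cleaned, ordered tokens.
#' @export
#' @examples
#' clean_tokens("A pump and a catheter", c("a", "and"))
clean_tokens <- function(section_text, stop_words = default_stopwords()) {
  stopifnot(is.character(section_text), length(section_text) == 1)
  if (is.na(section_text) || !nzchar(section_text)) return(character())
  toks <- strsplit(tolower(section_text), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  toks <- toks[nchar(toks) >= 2]
  toks[!(toks %in% stop_words)]
}

#' Parse one summary document
#'
#' Runs ID extraction, section segmentation and tokenisation on a raw
#' summary, returning the parsed record plus the cited predicate IDs.
#' The device's own ID is removed from the citation list by exact match;
#' all other extracted IDs are kept (citation sentences are not
#' distinguished from incidental mentions).
#'
#' @param raw_text Character scalar, the full summary text.
#' @param self_id The document's own device ID (must match the ID grammar).
#' @param stop_words Stop-word vector for tokenisation.
#' @param headings Heading synonym sets for segmentation.
#' @param unreadable_threshold Passed to [segment_sections()].
#' @return List of class `summary_document`: `device_id`, `raw_text`,
#'   `sections`, `tokens` (per-section cleaned token vectors),
#'   `parse_status`, `predicates`.
#' @export
parse_summary <- function(raw_text, self_id,
                          stop_words = default_stopwords(),
                          headings = default_headings(),
                          unreadable_threshold = 0.3) {
  self_id <- toupper(self_id)
  if (!is_device_id(self_id)) {
    stop("malformed device ID: ", self_id)
  }
  seg <- segment_sections(raw_text, headings, unreadable_threshold)
  preds <- setdiff(extract_device_ids(raw_text), self_id)
  tokens <- lapply(seg$sections, clean_tokens, stop_words = stop_words)
  structure(list(device_id = self_id,
                 raw_text = raw_text,
                 sections = seg$sections,
                 tokens = tokens,
                 parse_status = seg$parse_status,
                 predicates = preds),
            class = "summary_document")
}

#' Parse a directory of summary files
#'
#' Reads every `<device_id>.txt` file under `dir` and parses it with
#' [parse_summary()], using the file name as the device's own ID.
#'
#' @param dir Directory of UTF-8 `.txt` summaries named `<device_id>.txt`.
#' @inheritParams parse_summary
#' @return Named list of `summary_document` records, keyed by device ID.
#' @export
parse_corpus_dir <- function(dir, stop_words = default_stopwords(),
                             headings = default_headings(),
                             unreadable_threshold = 0.3) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (length(files) == 0) stop("ingest: no .txt summaries found in ", dir)
  docs <- lapply(files, function(f) {
    id <- toupper(sub("\\.txt$", "", basename(f)))
    txt <- paste(readLines(f, warn = FALSE, encoding = "UTF-8"),
                 collapse = "\n")
    parse_summary(txt, id, stop_words, headings, unreadable_threshold)
  })
  names(docs) <- vapply(docs, `[[`, character(1), "device_id")
  docs
}

#' Write a parsed corpus as JSON-lines
#'
#' One JSON record per device: id, parse status, section bodies, predicate
#' list. This is the file-based hand-off between the ingest stage and the
#' graph/similarity stages.
#'
#' @param docs Named list of `summary_document` records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parsed_jsonl <- function(docs, path) {
  lines <- vapply(docs, function(d) {
    jsonlite::toJSON(list(device_id = d$device_id,
                          parse_status = d$parse_status,
                          sections = d$sections,
                          predicates = d$predicates),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
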