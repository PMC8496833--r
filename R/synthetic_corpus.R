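# Synthetic 510(k)-style corpus with planted genealogy, mutation-controlled
# section similarity, and heavy-tailed product-code surveillance counts.

#' Configuration for the synthetic corpus generator
#'
#' Defines the study conditions the generator emulates: a sparse genealogy
#' where most devices cite one or two predicates, De Novo-rooted lineages
#' (one founder per product code), section texts whose pairwise similarity
#' is controlled by a per-edge word-mutation rate, and product-code
#' complaint counts with a heavy tail and planted outlier codes.
#'
#' @param n_devices Total number of devices (roots included).
#' @param n_roots Number of De Novo-style founder devices (`DEN......` IDs).
#'   Must be at least `n_procodes` so every product code has a founder.
#' @param year_min,year_max Decision-year range; roots are cleared in
#'   `year_min`, descendants strictly later.
#' @param predicate_count_pmf Named numeric vector: probability mass over
#'   the number of predicates a non-root device cites (names are integer
#'   counts >= 1; must sum to 1). Default puts 0.8 mass on 1-2 predicates
#'   with a geometric-style tail.
#' @param mutation_rate_range `c(lo, hi)` in \[0, 1\]: each non-root device
#'   draws a substitution probability uniformly from this range and applies
#'   it independently to every content word copied from its text-donor
#'   predicate.
#' @param vocab_size Total number of distinct content words (shared pool +
#'   per-code jargon pools + disjoint novel-jargon mutation pool).
#' @param n_procodes Number of three-letter product codes.
#' @param n_outlier_procodes Product codes planted with complaint-to-device
#'   ratios exceeding every other code.
#' @param n_recalled Devices given Class-1 recalls (drawn from outlier
#'   codes when any are planted).
#' @param section_words Words per section body for root devices.
#' @param shared_fraction Fraction of each root section drawn from the
#'   vocabulary pool shared across product codes (the rest is code jargon).
#' @param ocr_noise_frac Fraction of devices whose emitted summary is
#'   corrupted with non-ASCII garbage, to exercise the unreadable-document
#'   parser path. Default 0 (no corruption).
#' @param seed Integer RNG seed; the whole corpus is a pure function of the
#'   configuration including this seed.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_devices = 500L,
                             n_roots = 12L,
                             year_min = 1997L,
                             year_max = 2020L,
                             predicate_count_pmf = c(
                               "1" = 0.55, "2" = 0.25, "3" = 0.10,
                               "4" = 0.05, "5" = 0.03, "6" = 0.02),
                             mutation_rate_range = c(0.05, 0.5),
                             vocab_size = 2000L,
                             n_procodes = 12L,
                             n_outlier_procodes = 2L,
                             n_recalled = 8L,
                             section_words = c(indications_for_use = 60L,
                                               device_description = 80L),
                             shared_fraction = 0.2,
                             ocr_noise_frac = 0,
                             seed = 1L) {
  cfg <- structure(as.list(environment()), class = "generator_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  pmf <- cfg$predicate_count_pmf
  ks <- suppressWarnings(as.numeric(names(pmf)))
  if (anyNA(ks) || any(ks < 1) || any(ks != floor(ks))) {
    stop("predicate_count_pmf must be named by integers >= 1")
  }
  if (abs(sum(pmf) - 1) > 1e-9 || any(pmf < 0)) {
    stop("predicate_count_pmf must be a probability mass function (sum 1)")
  }
  if (cfg$n_roots < 1) stop("n_roots must be >= 1")
  if (cfg$n_devices < cfg$n_roots) stop("n_devices must be >= n_roots")
  if (cfg$year_min > cfg$year_max) stop("year_min must be <= year_max")
  mr <- cfg$mutation_rate_range
  if (length(mr) != 2 || mr[1] < 0 || mr[2] > 1 || mr[1] > mr[2]) {
    stop("mutation_rate_range must be c(lo, hi) within [0, 1]")
  }
  if (cfg$n_procodes < 1 || cfg$n_outlier_procodes > cfg$n_procodes) {
    stop("need 0 <= n_outlier_procodes <= n_procodes >= 1")
  }
  if (cfg$n_roots < cfg$n_procodes) {
    stop("n_roots must be >= n_procodes so every product code has a founder")
  }
  if (cfg$n_devices > cfg$n_roots && cfg$year_max == cfg$year_min) {
    stop("infeasible config: non-root devices exist but the year range ",
         "cannot order any edge (year_min == year_max)")
  }
  need_jargon <- ceiling(max(cfg$section_words) * (1 - cfg$shared_fraction))
  need_shared <- ceiling(max(cfg$section_words) * cfg$shared_fraction)
  per_code <- floor(0.42 * cfg$vocab_size / cfg$n_procodes)
  n_shared <- max(20L, round(0.08 * cfg$vocab_size))
  if (per_code < need_jargon || n_shared < need_shared) {
    stop("vocab_size too small for the requested section lengths")
  }
  invisible(cfg)
}

# Pronounceable pseudo-words: 3-5 consonant+vowel syllables, deduplicated.
make_vocabulary <- function(n, seed) {
  with_seed(seed, {
    cons <- c("b","c","d","f","g","l","m","n","p","r","s","t","v","z")
    vow <- c("a","e","i","o","u")
    words <- character(0)
    while (length(words) < n) {
      k <- n - length(words)
      syl <- sample(3:5, 2 * k, replace = TRUE)
      new <- vapply(syl, function(s) {
        paste0(sample(cons, s, replace = TRUE),
               sample(vow, s, replace = TRUE), collapse = "")
      }, character(1))
      words <- unique(c(words, new))
    }
    words[seq_len(n)]
  })
}

make_procodes <- function(n, seed) {
  with_seed(seed, {
    codes <- character(0)
    while (length(codes) < n) {
      new <- vapply(seq_len(2 * (n - length(codes))), function(i) {
        paste0(sample(LETTERS, 3, replace = TRUE), collapse = "")
      }, character(1))
      codes <- unique(c(codes, new))
    }
    codes[seq_len(n)]
  })
}

# Deterministic rendering of a token bag into sentence-like body text:
# identical token vectors render to identical bodies.
render_body <- function(tokens) {
  if (length(tokens) == 0) return("")
  groups <- split(tokens, ceiling(seq_along(tokens) / 10))
  sentences <- vapply(groups, function(g) {
    s <- paste(g, collapse = " ")
    paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)), ".")
  }, character(1))
  paste(sentences, collapse = " ")
}

#' Render a summary document from sections and predicate citations
#'
#' Emits plain text mimicking the layout of a public 510(k) summary: a
#' header carrying the device's own ID, one substantial-equivalence
#' citation sentence per predicate, then the two headed sections. The
#' output round-trips through [parse_summary()]: the parser recovers
#' exactly the input predicate IDs and section bodies.
#'
#' @param device_id The device's own ID (`K` or `DEN` + six digits).
#' @param sections Named list with non-empty `indications_for_use` and
#'   `device_description` body strings.
#' @param predicate_ids Character vector of cited predicate IDs (possibly
#'   empty).
#' @return Character scalar, the rendered document.
#' @export
render_summary_text <- function(device_id, sections, predicate_ids = character()) {
  device_id <- toupper(device_id)
  if (!is_device_id(device_id)) stop("malformed device ID: ", device_id)
  bad <- predicate_ids[!is_device_id(toupper(predicate_ids))]
  if (length(bad)) stop("malformed predicate ID(s): ", paste(bad, collapse = ", "))
  stopifnot(all(c("indications_for_use", "device_description") %in% names(sections)),
            nzchar(sections$indications_for_use),
            nzchar(sections$device_description))
  cites <- if (length(predicate_ids)) {
    paste0(vapply(toupper(predicate_ids), function(p) {
      sprintf("The subject device is substantially equivalent to the legally marketed predicate device %s.", p)
    }, character(1)), collapse = "\n")
  } else {
    "No predicate device is cited in this summary."
  }
  paste0(
    "510(k) SUMMARY\n\n",
    "Submission Number: ", device_id, "\n\n",
    "Predicate Devices:\n", cites, "\n\n",
    "Indications for Use:\n", sections$indications_for_use, "\n\n",
    "Device Description:\n", sections$device_description, "\n"
  )
}

#' Generate a synthetic 510(k)-style corpus
#'
#' Produces a metadata table, one summary document per device, the planted
#' ground truth, and a product-code surveillance table, all as a pure
#' function of the configuration (two runs with the same config are
#' byte-identical). Each product code is founded by a De Novo root with
#' fresh template text (a bag of words drawn without replacement from a
#' shared pool plus code-specific jargon). Every other device copies the
#' sections of one same-code predicate (its text donor) and substitutes
#' each content word independently, with the edge's mutation rate, by a
#' word from a disjoint novel-jargon pool; additional predicate citations
#' are drawn from earlier same-code devices. Complaint counts are
#' heavy-tailed (log-normal), and planted outlier codes are scaled so their
#' complaint-to-device ratio strictly exceeds every other code's.
#'
#' @param config A [generator_config()].
#' @return List of class `synthetic_corpus` with elements `metadata`
#'   (data.frame: device_id, decision_year, product_code,
#'   summary_available), `summaries` (named character vector of raw
#'   document texts), `ground_truth` (list: true_edges data.frame with
#'   per-edge mutation rate where defined, outlier_procodes, recalled_ids),
#'   and `surveillance` (data.frame with the documented columns).
#' @export
generate_corpus <- function(config = generator_config()) {
  validate_config(config)
  cfg <- config
  n <- cfg$n_devices
  is_root <- seq_len(n) <= cfg$n_roots
  ids <- ifelse(is_root, sprintf("DEN%06d", seq_len(n)),
                sprintf("K%06d", seq_len(n)))

  # vocabulary pools: shared / per-code jargon / disjoint novel jargon
  vocab <- make_vocabulary(cfg$vocab_size, substream_seed(cfg$seed, 0, "vocab"))
  n_shared <- max(20L, round(0.08 * cfg$vocab_size))
  n_novel <- round(0.5 * cfg$vocab_size)
  shared_pool <- vocab[seq_len(n_shared)]
  novel_pool <- vocab[seq.int(cfg$vocab_size - n_novel + 1, cfg$vocab_size)]
  jargon <- vocab[seq.int(n_shared + 1, cfg$vocab_size - n_novel)]
  procodes <- make_procodes(cfg$n_procodes, substream_seed(cfg$seed, 0, "codes"))
  code_pool <- split(jargon, rep_len(seq_len(cfg$n_procodes), length(jargon)))
  names(code_pool) <- procodes

  # pass 1: per-device attributes (year, lineage code) from device substreams
  year <- integer(n)
  code <- character(n)
  root_code <- procodes[rep_len(seq_len(cfg$n_procodes), cfg$n_roots)]
  for (i in seq_len(n)) {
    if (is_root[i]) {
      year[i] <- cfg$year_min
      code[i] <- root_code[i]
    } else {
      a <- with_seed(substream_seed(cfg$seed, i, "attrs"), {
        list(year = sample(seq.int(cfg$year_min + 1L, cfg$year_max), 1),
             code = sample(procodes, 1))
      })
      year[i] <- a$year
      code[i] <- a$code
    }
  }

  # pass 2: edges and section texts in year-then-index order so every text
  # donor has already been generated
  order_idx <- order(year, seq_len(n))
  pmf_k <- as.integer(names(cfg$predicate_count_pmf))
  sections <- vector("list", n)
  edges <- vector("list", n)
  for (i in order_idx) {
    if (is_root[i]) {
      sections[[i]] <- with_seed(substream_seed(cfg$seed, i, "text"), {
        lapply(cfg$section_words, function(L) {
          n_sh <- round(cfg$shared_fraction * L)
          c(sample(shared_pool, n_sh),
            sample(code_pool[[code[i]]], L - n_sh))
        })
      })
      next
    }
    eligible <- which(code == code[i] & year < year[i])
    stopifnot(length(eligible) >= 1)  # every code has a root at year_min
    link <- with_seed(substream_seed(cfg$seed, i, "links"), {
      k <- sample(pmf_k, 1, prob = cfg$predicate_count_pmf)
      k <- min(k, length(eligible))
      preds <- if (length(eligible) == 1) eligible else sample(eligible, k)
      rate <- runif(1, cfg$mutation_rate_range[1], cfg$mutation_rate_range[2])
      list(preds = preds, rate = rate)
    })
    donor <- link$preds[1]
    sections[[i]] <- with_seed(substream_seed(cfg$seed, i, "text"), {
      lapply(sections[[donor]], function(toks) {
        hit <- runif(length(toks)) < link$rate
        if (any(hit)) {
          repl <- sample(setdiff(novel_pool, toks), sum(hit))
          toks[hit] <- repl
        }
        toks
      })
    })
    edges[[i]] <- data.frame(
      descendant_id = ids[i],
      predicate_id = ids[link$preds],
      mutation_rate = c(link$rate, rep(NA_real_, length(link$preds) - 1)),
      stringsAsFactors = FALSE)
  }

  true_edges <- do.call(rbind, edges[!vapply(edges, is.null, logical(1))])
  if (is.null(true_edges)) {
    true_edges <- data.frame(descendant_id = character(),
                             predicate_id = character(),
                             mutation_rate = numeric())
  }
  rownames(true_edges) <- NULL

  # summaries, optionally corrupting a fraction with OCR-style garbage
  summaries <- vapply(seq_len(n), function(i) {
    body <- lapply(sections[[i]], render_body)
    names(body) <- names(cfg$section_words)
    preds <- if (is_root[i]) character() else
      edges[[i]]$predicate_id
    render_summary_text(ids[i], body, preds)
  }, character(1))
  names(summaries) <- ids
  if (cfg$ocr_noise_frac > 0) {
    noisy <- with_seed(substream_seed(cfg$seed, 0, "noise"), {
      sample(n, round(cfg$ocr_noise_frac * n))
    })
    for (i in noisy) {
      summaries[i] <- with_seed(substream_seed(cfg$seed, i, "noise"), {
        garble_text(summaries[i])
      })
    }
  }

  metadata <- data.frame(device_id = ids, decision_year = year,
                         product_code = code, summary_available = 1L,
                         stringsAsFactors = FALSE)

  surv <- make_surveillance(cfg, metadata, procodes)

  structure(list(
    metadata = metadata,
    summaries = summaries,
    ground_truth = list(true_edges = true_edges,
                        outlier_procodes = surv$outlier_procodes,
                        recalled_ids = surv$recalled_ids),
    surveillance = surv$table,
    config = cfg
  ), class = "synthetic_corpus")
}

# Replace most alphanumeric characters with non-ASCII garbage, emulating
# failed OCR of a scanned page.
garble_text <- function(text) {
  chars <- strsplit(text, "")[[1]]
  garbage <- intToUtf8(c(161:191, 9600:9631), multiple = TRUE)
  hit <- runif(length(chars)) < 0.6 & grepl("[a-zA-Z0-9]", chars)
  chars[hit] <- sample(garbage, sum(hit), replace = TRUE)
  paste(chars, collapse = "")
}

make_surveillance <- function(cfg, metadata, procodes) {
  with_seed(substream_seed(cfg$seed, 0, "surv"), {
    device_count <- as.integer(table(factor(metadata$product_code,
                                            levels = procodes)))
    # heavy-tailed complaint counts: a few codes dominate
    dc <- round(rlnorm(cfg$n_procodes, meanlog = 5, sdlog = 1.6))
    pc <- round(dc * runif(cfg$n_procodes, 0.5, 0.9))
    outliers <- if (cfg$n_outlier_procodes > 0) {
      sort(sample(procodes, cfg$n_outlier_procodes))
    } else character()
    idx_out <- procodes %in% outliers
    if (any(idx_out)) {
      base_ratio <- max((dc / pmax(device_count, 1))[!idx_out], 1)
      scale <- runif(sum(idx_out), 5, 20)
      dc[idx_out] <- ceiling(device_count[idx_out] * base_ratio * scale)
      pc[idx_out] <- round(dc[idx_out] * runif(sum(idx_out), 0.5, 0.9))
    }
    # Class-1 recalls concentrate in outlier codes when any are planted
    pool <- if (length(outliers)) {
      metadata$device_id[metadata$product_code %in% outliers]
    } else metadata$device_id
    if (cfg$n_recalled > length(pool)) {
      stop("infeasible config: n_recalled exceeds devices in outlier codes")
    }
    recalled <- sort(sample(pool, cfg$n_recalled))
    rc1 <- as.integer(table(factor(
      metadata$product_code[metadata$device_id %in% recalled],
      levels = procodes)))
    tab <- data.frame(
      product_code = procodes,
      device_count = device_count,
      device_complaints = as.integer(dc),
      patient_complaints = as.integer(pc),
      recalls_class1 = rc1,
      recalls_class2 = rpois(cfg$n_procodes, 2),
      recalls_class3 = rpois(cfg$n_procodes, 1),
      stringsAsFactors = FALSE)
    tab <- tab[order(tab$product_code), ]
    rownames(tab) <- NULL
    list(table = tab, outlier_procodes = outliers, recalled_ids = recalled)
  })
}

#' Write a synthetic corpus to disk
#'
#' Emits the external interface of the generator: `metadata.csv`, one UTF-8
#' `<device_id>.txt` summary per device under `summaries/`,
#' `surveillance.csv`, and `ground_truth.json` (edge list with per-edge
#' mutation rate, outlier codes, recalled IDs).
#'
#' @param corpus A `synthetic_corpus` from [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(file.path(dir, "summaries"), recursive = TRUE, showWarnings = FALSE)
  write.csv(corpus$metadata, file.path(dir, "metadata.csv"), row.names = FALSE)
  write.csv(corpus$surveillance, file.path(dir, "surveillance.csv"),
            row.names = FALSE)
  for (id in names(corpus$summaries)) {
    writeLines(corpus$summaries[[id]],
               file.path(dir, "summaries", paste0(id, ".txt")),
               useBytes = TRUE)
  }
  jsonlite::write_json(corpus$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       dataframe = "rows", na = "null", auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
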