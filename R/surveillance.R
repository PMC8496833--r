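# Product-code complaint/recall surveillance: loading and validation,
# complaint-to-device ratios, outlier identification, recalled-vs-marketed
# similarity comparison, and scatter-ready tables.

SURV_COLS <- c("product_code", "device_count", "device_complaints",
               "patient_complaints", "recalls_class1", "recalls_class2",
               "recalls_class3")

#' Load a product-code surveillance table
#'
#' Reads a TPLC-style CSV (one row per product code: device count,
#' device/patient complaint counts, recall counts by class I/II/III) and
#' validates it. A missing required column is a hard failure; malformed
#' rows (negative counts, non-integer values, zero devices with recorded
#' complaints or recalls) are rejected individually with line-numbered
#' diagnostics.
#'
#' @param csv Path to the CSV file.
#' @return Validated data.frame of class `product_code_stats`; attribute
#'   `rejected` carries the diagnostics for dropped rows.
#' @export
load_surveillance <- function(csv) {
  raw <- read.csv(csv, stringsAsFactors = FALSE)
  missing <- setdiff(SURV_COLS, names(raw))
  if (length(missing)) {
    stop("surveillance CSV missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  raw <- raw[, SURV_COLS]
  count_cols <- SURV_COLS[-1]
  bad <- character(0)
  keep <- rep(TRUE, nrow(raw))
  for (i in seq_len(nrow(raw))) {
    vals <- suppressWarnings(as.numeric(raw[i, count_cols]))
    why <- NULL
    if (anyNA(vals) || any(vals < 0) || any(vals != floor(vals))) {
      why <- "counts must be non-negative integers"
    } else if (vals[1] < 1 && any(vals[-1] > 0)) {
      why <- "zero devices but complaints/recalls recorded"
    } else if (!grepl("^[A-Z]{3}$", raw$product_code[i])) {
      why <- "product code must match [A-Z]{3}"
    }
    if (!is.null(why)) {
      keep[i] <- FALSE
      bad <- c(bad, sprintf("row %d (%s): %s", i, raw$product_code[i], why))
    }
  }
  if (length(bad)) {
    warning("rejected ", length(bad), " surveillance row(s):\n",
            paste(bad, collapse = "\n"))
  }
  out <- raw[keep, , drop = FALSE]
  out[count_cols] <- lapply(out[count_cols], as.integer)
  rownames(out) <- NULL
  structure(out, rejected = bad, class = c("product_code_stats", "data.frame"))
}

#' Complaint-to-device ratio
#'
#' Complaints per marketed device for each product code; the ranking
#' statistic used to flag outlier codes.
#'
#' @param stats `product_code_stats` data.frame (or any data.frame with
#'   the surveillance columns).
#' @param type `"device"` (device complaints, default) or `"patient"`.
#' @return Named numeric vector of ratios (names = product codes); codes
#'   with zero devices get `NA` with a warning.
#' @export
complaint_device_ratio <- function(stats, type = c("device", "patient")) {
  type <- match.arg(type)
  num <- if (type == "device") stats$device_complaints else
    stats$patient_complaints
  ratio <- ifelse(stats$device_count >= 1, num / stats$device_count, NA_real_)
  if (anyNA(ratio)) {
    warning("undefined ratio for code(s) with zero devices: ",
            paste(stats$product_code[is.na(ratio)], collapse = ", "))
  }
  setNames(ratio, stats$product_code)
}

#' Identify outlier product codes
#'
#' The k product codes with the highest complaint-to-device ratio; ties
#' broken by total complaints (device + patient), then lexicographically
#' by code, so the result is deterministic and invariant to row order.
#'
#' @param stats `product_code_stats` data.frame.
#' @param k Number of outliers to return (default 7).
#' @param type Ratio variant, see [complaint_device_ratio()].
#' @return Character vector of k product codes, highest ratio first.
#' @export
identify_outliers <- function(stats, k = 7L, type = c("device", "patient")) {
  type <- match.arg(type)
  if (k > nrow(stats)) {
    stop("k = ", k, " exceeds the ", nrow(stats), " available product codes")
  }
  ratio <- complaint_device_ratio(stats, type)
  total <- stats$device_complaints + stats$patient_complaints
  ord <- order(-ratio, -total, stats$product_code, na.last = TRUE)
  stats$product_code[ord][seq_len(k)]
}

#' Compare recalled devices to marketed devices by text similarity
#'
#' Scores every (recalled, marketed) pair with the combined two-section
#' similarity, reports per-recalled-device means and the overall mean, and
#' flags whether every recalled device's mean similarity stays below the
#' threshold — the condition under which no marketed device shows
#' substantial textual equivalence to a recalled one.
#'
#' @param recalled_ids,marketed_ids Non-empty character vectors of device
#'   IDs; devices without a parsed (`parse_status == "ok"`) summary are
#'   excluded and counted.
#' @param docs Named list of `summary_document` records.
#' @param method,model Passed to [device_similarity()].
#' @param threshold Mean-similarity threshold for the flag (default 0.5).
#' @return List: `matrix` (recalled x marketed combined scores),
#'   `per_recalled_mean`, `overall_mean`, `below_threshold` (logical),
#'   `threshold`, `n_excluded`.
#' @export
recalled_vs_marketed <- function(recalled_ids, marketed_ids, docs,
                                 method = c("bow", "embedding"),
                                 model = NULL, threshold = 0.5) {
  method <- match.arg(method)
  if (length(recalled_ids) == 0 || length(marketed_ids) == 0) {
    stop("recalled and marketed sets must both be non-empty")
  }
  usable <- function(ids) {
    ok <- vapply(ids, function(id) {
      !is.null(docs[[id]]) && identical(docs[[id]]$parse_status, "ok")
    }, logical(1))
    ids[ok]
  }
  rec <- usable(recalled_ids)
  mkt <- usable(marketed_ids)
  n_excluded <- (length(recalled_ids) - length(rec)) +
    (length(marketed_ids) - length(mkt))
  if (length(rec) == 0 || length(mkt) == 0) {
    stop("no parsable summaries left in the recalled or marketed set")
  }
  m <- matrix(NA_real_, length(rec), length(mkt), dimnames = list(rec, mkt))
  for (r in rec) {
    for (g in mkt) {
      s <- device_similarity(docs[[r]], docs[[g]], method, model)
      m[r, g] <- unname(s$scores["combined"])
    }
  }
  per <- rowMeans(m)
  list(matrix = m,
       per_recalled_mean = per,
       overall_mean = mean(m),
       below_threshold = all(per < threshold),
       threshold = threshold,
       n_excluded = n_excluded)
}

#' Long-format recalls/complaints scatter table
#'
#' One row per (product code, recall class) with the recall count, the
#' log10(x + 1)-scaled complaint counts (the +1 admits zero counts) and
#' the device count; ready for a complaints-versus-recalls scatter plot
#' where point size encodes the number of devices in the code.
#'
#' @param stats `product_code_stats` data.frame.
#' @return Data frame `product_code`, `recall_class`, `recall_count`,
#'   `log10_device_complaints`, `log10_patient_complaints`,
#'   `device_count`; 3 rows per code.
#' @export
scatter_table <- function(stats) {
  rows <- lapply(1:3, function(cl) {
    data.frame(product_code = stats$product_code,
               recall_class = cl,
               recall_count = stats[[paste0("recalls_class", cl)]],
               log10_device_complaints = log10(stats$device_complaints + 1),
               log10_patient_complaints = log10(stats$patient_complaints + 1),
               device_count = stats$device_count,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$product_code, out$recall_class), ]
  rownames(out) <- NULL
  out
}
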