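#' Read a paired-assessment study table from CSV
#'
#' Expects a UTF-8 CSV with header
#' `subject_id,item_id,response_a,response_b`; responses are integer
#' codes `1..m` or exact scale labels, blank/NA meaning missing.
#' Incomplete records are retained for accounting but excluded from
#' analysis (pairwise-complete deletion per item, so per-item n varies).
#'
#' @param path Path to the CSV file.
#' @param scale A [response_scale()]; default [icf_qualifier_scale()].
#' @return A `study_data` data frame (integer codes, NA = missing) with
#'   attribute `scale`.
#' @export
read_study_csv <- function(path, scale = icf_qualifier_scale()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, check.names = TRUE)
  need <- c("subject_id", "item_id", "response_a", "response_b")
  if (!all(need %in% names(raw)))
    stop("missing required columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  key <- paste(raw$subject_id, raw$item_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop(sprintf("duplicate (subject, item) record at row %d: (%s, %s)",
                 d, raw$subject_id[d], raw$item_id[d]))
  }
  a <- decode_responses(raw$response_a, scale)
  b <- decode_responses(raw$response_b, scale)
  for (side in c("a", "b")) {
    bad <- attr(if (side == "a") a else b, "bad")
    if (length(bad))
      stop(sprintf("row %d: response_%s '%s' is neither a code in 1..%d nor a scale label",
                   bad[1], side,
                   (if (side == "a") raw$response_a else raw$response_b)[bad[1]],
                   scale$m))
  }
  out <- data.frame(subject_id = raw$subject_id, item_id = raw$item_id,
                    response_a = as.integer(a), response_b = as.integer(b),
                    stringsAsFactors = FALSE)
  attr(out, "scale") <- scale
  class(out) <- c("study_data", "data.frame")
  out
}

#' Study analysis configuration
#'
#' Fixes the two things a report must never leave ambiguous: the RP
#' orientation and the resampling plan.  In `inter-scale` mode a
#' positive RP means the *second* questionnaire (`response_b`) attracts
#' higher categories; in `patient-observer` mode the patient self-report
#' is `response_a`, the observer `response_b`, and a positive RP means
#' the *patient* assesses higher levels — matching the reporting
#' convention of patient-vs-professional comparisons.  The convention in
#' force is printed in every report header.
#'
#' @param mode `"inter-scale"` or `"patient-observer"`.
#' @param scale A [response_scale()].
#' @param plan A [resampling_plan()].
#' @param spearman Logical; compute r_s per item.  Default: TRUE in
#'   inter-scale mode, FALSE in patient-observer mode.
#' @return An object of class `study_config`.
#' @export
study_config <- function(mode = c("inter-scale", "patient-observer"),
                         scale = icf_qualifier_scale(),
                         plan = resampling_plan(seed = 1L),
                         spearman = NULL) {
  mode <- match.arg(mode)
  if (is.null(spearman)) spearman <- mode == "inter-scale"
  positive <- if (mode == "inter-scale") "b" else "a"
  structure(list(mode = mode, scale = scale, plan = plan,
                 spearman = isTRUE(spearman), positive = positive),
            class = "study_config")
}

#' Analyse one item's paired assessments
#'
#' Computes PA, RP with CI, RV with CI, D, and optionally r_s, with RP
#' oriented so that a positive value means the configured `positive`
#' source used higher categories.  All values in full precision;
#' rounding is deferred to [write_results()].
#'
#' @param pairs A [paired_assessments()] collection (n >= 2).
#' @param plan A [resampling_plan()].
#' @param positive `"b"` (default: positive RP = second source higher)
#'   or `"a"` (positive RP = first source higher).  Flipping negates RP
#'   and leaves every other measure unchanged.
#' @param spearman Logical, compute r_s (NA with a note if degenerate).
#' @param item Item identifier carried into the result.
#' @return An object of class `item_result`.
#' @export
analyze_item <- function(pairs, plan, positive = c("b", "a"),
                         spearman = TRUE, item = "item") {
  positive <- match.arg(positive)
  if (!inherits(pairs, "paired_assessments"))
    stop("analyze_item needs a paired_assessments collection")
  n <- nrow(pairs)
  if (n < 2) stop("item needs at least 2 complete pairs")
  if (positive == "a")  # orient RP by swapping the two sources
    pairs <- paired_assessments(pairs$subject_id, pairs$b, pairs$a,
                                scale = attr(pairs, "scale"))
  tab <- contingency_from_pairs(pairs)
  rs <- NULL
  note <- NULL
  if (spearman) {
    rs <- tryCatch(spearman_rho(pairs), error = function(e) {
      note <<- conditionMessage(e)
      measure_value(NA_real_, "rs")
    })
  }
  structure(list(
    item = item, n = n,
    pa = percentage_agreement(tab),
    rp = resample_ci(pairs, "RP", plan),
    rv = resample_ci(pairs, "RV", plan),
    d  = disorder_measure(tab),
    rs = rs, note = note,
    positive = positive,
    table = tab), class = "item_result")
}

#' @export
print.item_result <- function(x, ...) {
  cat(sprintf("Item %s (n = %d): PA %.0f%%, RP %.2f (%.2f to %.2f), RV %.2f (%.2f to %.2f), D %.2f",
              x$item, x$n, 100 * x$pa$estimate,
              x$rp$estimate, x$rp$lower, x$rp$upper,
              x$rv$estimate, x$rv$lower, x$rv$upper, x$d$estimate))
  if (!is.null(x$rs) && !is.na(x$rs$estimate))
    cat(sprintf(", r_s %.2f", x$rs$estimate))
  cat("\n")
  invisible(x)
}

#' Analyse every item of a study
#'
#' Splits the study table by item, applies pairwise-complete deletion,
#' analyses each item with [analyze_item()] (each item gets its own
#' deterministic bootstrap sub-seed derived from the plan seed), and
#' summarises PA, RP, RV and D across items by median and range.
#' Degenerate items (fewer than 2 complete pairs) become structured skip
#' records instead of aborting the study.
#'
#' @param study A `study_data` data frame from [read_study_csv()] or
#'   [generate_study()].
#' @param config A [study_config()].
#' @return An object of class `study_result`: list with `items` (list of
#'   `item_result`), `skipped` (data frame of item/reason), `summary`
#'   (a `study_summary`), `config`, and per-item exclusion accounting.
#' @export
analyze_study <- function(study, config = study_config()) {
  stopifnot(inherits(study, "study_data") || is.data.frame(study))
  scale <- attr(study, "scale")
  if (is.null(scale)) scale <- config$scale
  ids <- unique(study$item_id)
  results <- list()
  skipped <- data.frame(item = character(), reason = character(),
                        stringsAsFactors = FALSE)
  excl <- stats::setNames(integer(length(ids)), ids)
  for (item in ids) {
    rows <- study[study$item_id == item, , drop = FALSE]
    ok <- !is.na(rows$response_a) & !is.na(rows$response_b)
    excl[item] <- sum(!ok)
    if (sum(ok) < 2) {
      skipped <- rbind(skipped, data.frame(
        item = item, reason = sprintf("only %d complete pairs", sum(ok)),
        stringsAsFactors = FALSE))
      next
    }
    pairs <- paired_assessments(rows$subject_id[ok], rows$response_a[ok],
                                rows$response_b[ok], scale = scale)
    item_plan <- config$plan
    if (item_plan$method == "bootstrap")
      item_plan$seed <- substream_seed(config$plan$seed, paste0("ci-", item))
    res <- tryCatch(
      analyze_item(pairs, item_plan, positive = config$positive,
                   spearman = config$spearman, item = item),
      error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- rbind(skipped, data.frame(item = item,
                                           reason = conditionMessage(res),
                                           stringsAsFactors = FALSE))
    } else results[[item]] <- res
  }
  if (!length(results)) stop("no analyzable items in study")
  structure(list(items = results, skipped = skipped,
                 summary = study_summary(results),
                 excluded = excl, config = config),
            class = "study_result")
}

#' Cross-item summary: median and range per measure
#'
#' @param items List of `item_result` objects.
#' @return An object of class `study_summary`: a data frame with one row
#'   per measure (PA, RP, RV, D) and columns median, min, max.
#' @export
study_summary <- function(items) {
  grab <- function(f) vapply(items, f, numeric(1))
  vals <- list(PA = grab(function(x) x$pa$estimate),
               RP = grab(function(x) x$rp$estimate),
               RV = grab(function(x) x$rv$estimate),
               D  = grab(function(x) x$d$estimate))
  out <- data.frame(measure = names(vals),
                    median = vapply(vals, stats::median, numeric(1)),
                    min = vapply(vals, min, numeric(1)),
                    max = vapply(vals, max, numeric(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("study_summary", "data.frame")
  out
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("Study analysis (%s mode): %d items analysed, %d skipped\n",
              x$config$mode, length(x$items), nrow(x$skipped)))
  cat(rp_convention(x$config), "\n")
  for (it in x$items) print(it)
  cat("Across items (median [range]):\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-2s %.2f [%.2f to %.2f]\n",
                s$measure[i], s$median[i], s$min[i], s$max[i]))
  invisible(x)
}

rp_convention <- function(config) {
  if (config$positive == "b")
    "RP convention: positive RP = second source (response_b) uses higher categories"
  else
    "RP convention: positive RP = first source (response_a) uses higher categories"
}

#' Render a contingency table for display
#'
#' Display orientation: the first assessment's categories run ascending
#' left to right, the second assessment's ascending bottom to top, so
#' the agreement diagonal runs from the lower left to the upper right
#' corner; diagonal cells are marked with `*` and marginal totals are
#' appended.
#'
#' @param table A [contingency_table()].
#' @param scale A [response_scale()]; defaults to the table's.
#' @param mark Marker appended to agreement-diagonal cells.
#' @return A character matrix (rows named by the second assessment's
#'   categories, top = highest; last row/column are marginal totals),
#'   suitable for `write.csv` or printing.
#' @export
render_contingency <- function(table, scale = attr(table, "scale"), mark = "*") {
  M <- as_table_matrix(table)
  m <- nrow(M)
  grid <- matrix("", m + 1, m + 1)
  for (j in seq_len(m)) {        # display row: second-assessment category, top = m
    cat_b <- m - j + 1L
    for (i in seq_len(m)) {
      v <- as.character(as.integer(M[i, cat_b]))
      if (i == cat_b) v <- paste0(v, mark)
      grid[j, i] <- v
    }
    grid[j, m + 1] <- as.character(as.integer(sum(M[, cat_b])))
  }
  grid[m + 1, seq_len(m)] <- as.character(as.integer(rowSums(M)))
  grid[m + 1, m + 1] <- as.character(as.integer(sum(M)))
  dimnames(grid) <- list(
    second = c(rev(scale$labels), "total"),
    first  = c(scale$labels, "total"))
  grid
}

fmt_ci <- function(mv, decimals = 2) {
  sprintf("%.*f (%.*f to %.*f)", decimals, mv$estimate,
          decimals, mv$lower, decimals, mv$upper)
}

#' Write a study report to CSV
#'
#' One row per item with the report-table formatting conventions:
#' PA as a whole percentage, other measures to `decimals` (default 2)
#' with CIs rendered as `(lo to hi)`; a summary block with cross-item
#' median and range; a footer recording the RP orientation, per-item
#' exclusion counts, the resampling plan and seed.
#'
#' @param results A `study_result` (or list of `item_result`s).
#' @param summary A `study_summary`; taken from `results` when missing.
#' @param path Output CSV path.
#' @param decimals Decimals for RP/RV/D/r_s (default 2).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, summary = NULL, path, decimals = 2) {
  if (inherits(results, "study_result")) {
    sr <- results
    items <- sr$items
    if (is.null(summary)) summary <- sr$summary
  } else {
    sr <- NULL
    items <- results
  }
  if (!length(items)) stop("no results to write")
  if (is.null(summary)) summary <- study_summary(items)

  fmt <- function(x) sprintf("%.*f", decimals, x)
  rows <- vapply(items, function(x) {
    paste(c(x$item, x$n,
            sprintf("%.0f%%", 100 * x$pa$estimate),
            fmt_ci(x$rp, decimals), fmt_ci(x$rv, decimals),
            fmt(x$d$estimate),
            if (is.null(x$rs)) "" else
              if (is.na(x$rs$estimate)) "NA" else fmt(x$rs$estimate)),
          collapse = ",")
  }, character(1))

  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# paired ordinal disagreement report")
  if (!is.null(sr)) wl("# ", rp_convention(sr$config))
  wl("item,n,PA,RP (95% CI),RV (95% CI),D,r_s")
  writeLines(unname(rows), con)
  wl("# summary: median and range across items")
  wl("measure,median,min,max")
  for (i in seq_len(nrow(summary))) {
    med <- summary$median[i]
    if (summary$measure[i] == "PA")
      wl(sprintf("PA,%.0f%%,%.0f%%,%.0f%%", 100 * med,
                 100 * summary$min[i], 100 * summary$max[i]))
    else
      wl(sprintf("%s,%s,%s,%s", summary$measure[i], fmt(med),
                 fmt(summary$min[i]), fmt(summary$max[i])))
  }
  if (!is.null(sr)) {
    wl("# footer")
    wl("# excluded incomplete records per item: ",
       paste(sprintf("%s=%d", names(sr$excluded), sr$excluded), collapse = " "))
    if (nrow(sr$skipped))
      for (i in seq_len(nrow(sr$skipped)))
        wl(sprintf("# skipped %s: %s", sr$skipped$item[i], sr$skipped$reason[i]))
    pl <- sr$config$plan
    wl(sprintf("# resampling: %s B=%d level=%g seed=%s", pl$method, pl$B,
               pl$level, if (is.null(pl$seed)) "none" else pl$seed))
  }
  invisible(path)
}
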