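#' Paired ordinal assessments for one item
#'
#' A collection of complete paired assessments: for each subject, the
#' category code given by the first source (`a`) and by the second
#' source (`b`), both on the same [response_scale()].  Subjects with a
#' missing response on either side must be excluded before construction
#' (pairwise-complete deletion happens in the pipeline layer, reducing
#' the per-item `n`).
#'
#' @param subject_id Vector of subject identifiers (unique).
#' @param a,b Integer category codes in `1..m` for the first and second
#'   assessment.
#' @param scale A [response_scale()]; defaults to the five-point
#'   [icf_qualifier_scale()].
#' @return An object of class `paired_assessments`: a data frame with
#'   columns `subject_id`, `a`, `b` and attribute `scale`.
#' @examples
#' pa <- paired_assessments(1:3, c(1, 2, 3), c(3, 2, 4))
#' nrow(pa)
#' @export
paired_assessments <- function(subject_id, a, b, scale = icf_qualifier_scale()) {
  if (length(a) != length(b) || length(a) != length(subject_id))
    stop("subject_id, a and b must have equal length")
  if (length(a) == 0L)
    stop("no complete pairs")
  a <- check_codes(a, scale, subject_id, "a")
  b <- check_codes(b, scale, subject_id, "b")
  if (anyDuplicated(subject_id))
    stop("duplicate subject_id in paired assessments")
  out <- data.frame(subject_id = subject_id, a = a, b = b,
                    stringsAsFactors = FALSE)
  attr(out, "scale") <- scale
  class(out) <- c("paired_assessments", "data.frame")
  out
}

check_codes <- function(x, scale, subject_id, side) {
  if (anyNA(x))
    stop(sprintf("missing response (%s) for subject %s: drop incomplete pairs first",
                 side, subject_id[which(is.na(x))[1]]))
  xi <- as.integer(x)
  if (any(xi != x))
    stop(sprintf("non-integer response (%s)", side))
  off <- which(xi < 1L | xi > scale$m)
  if (length(off))
    stop(sprintf("response %s = %d out of range 1..%d for subject %s",
                 side, xi[off[1]], scale$m, subject_id[off[1]]))
  xi
}

#' @export
print.paired_assessments <- function(x, ...) {
  sc <- attr(x, "scale")
  cat(sprintf("Paired ordinal assessments: n = %d subjects on an m = %d scale\n",
              nrow(x), sc$m))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Square contingency table of paired assessments
#'
#' The m-by-m table of pair frequencies `n_ij`, with rows indexing the
#' first assessment's category `i` and columns the second assessment's
#' category `j`.  All disagreement measures are computed from this
#' object.  For a display with the agreement diagonal running from the
#' lower left to the upper right corner see [render_contingency()].
#'
#' @param counts An m-by-m matrix of non-negative integer counts.
#' @param scale Optional [response_scale()] (inferred as an unlabelled
#'   m-category scale when absent).
#' @return An object of class `contingency_table`: the integer count
#'   matrix with attribute `scale`.
#' @export
contingency_table <- function(counts, scale = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stop("contingency table must be square")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) < 1)
    stop("contingency table must contain at least one pair")
  m <- nrow(counts)
  if (is.null(scale))
    scale <- response_scale(as.character(seq_len(m)))
  if (scale$m != m)
    stop(sprintf("table dimension %d does not match scale with m = %d", m, scale$m))
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(first = scale$labels, second = scale$labels)
  structure(counts, scale = scale, class = "contingency_table")
}

#' Build a contingency table from paired assessments
#'
#' @param pairs A [paired_assessments()] collection.
#' @param scale Scale to tabulate on; defaults to the scale attached to
#'   `pairs`.
#' @return A [contingency_table()] with `n_ij` = number of subjects with
#'   `a = i`, `b = j`; the total equals the number of pairs.
#' @examples
#' pa <- paired_assessments(1:3, c(1, 2, 3), c(3, 2, 4))
#' contingency_from_pairs(pa)
#' @export
contingency_from_pairs <- function(pairs, scale = attr(pairs, "scale")) {
  if (is.null(pairs) || nrow(pairs) == 0L)
    stop("no complete pairs")
  m <- scale$m
  counts <- matrix(tabulate((pairs$a - 1L) * m + pairs$b, nbins = m * m),
                   nrow = m, ncol = m, byrow = TRUE)
  contingency_table(counts, scale)
}

#' @export
print.contingency_table <- function(x, ...) {
  sc <- attr(x, "scale")
  cat(sprintf("Paired contingency table (n = %d), rows = first assessment, cols = second:\n",
              as.integer(sum(x))))
  print(matrix(as.integer(x), nrow(x), dimnames = dimnames(x)))
  invisible(x)
}

# transpose keeping class/scale (swaps the two assessment sources)
transpose_table <- function(tab) {
  contingency_table(t(unclass(tab)), attr(tab, "scale"))
}

as_table_matrix <- function(x) {
  if (inherits(x, "paired_assessments"))
    x <- contingency_from_pairs(x)
  if (!inherits(x, "contingency_table"))
    stop("expected a contingency_table or paired_assessments object")
  M <- unclass(x)
  attributes(M) <- list(dim = dim(x))
  M
}

#' Marginal distributions of a contingency table
#'
#' The two sets of marginal frequencies describe the distribution of
#' each set of assessments; systematic disagreement is a difference
#' between them.
#'
#' @param table A [contingency_table()].
#' @return A list with components `first` and `second`, each of class
#'   `marginal_distribution` holding proportions `p` and cumulative
#'   proportions `cum` (with `cum[m] = 1`).
#' @examples
#' tab <- contingency_table(matrix(1, 5, 5))
#' marginals(tab)$first$p
#' @export
marginals <- function(table) {
  M <- as_table_matrix(table)
  n <- sum(M)
  sc <- attr(table, "scale")
  mk <- function(p) structure(list(p = p, cum = cumsum(p), scale = sc),
                              class = "marginal_distribution")
  list(first = mk(rowSums(M) / n), second = mk(colSums(M) / n))
}

#' @export
print.marginal_distribution <- function(x, ...) {
  cat("Marginal distribution over", length(x$p), "ordered categories:\n")
  out <- rbind(p = round(x$p, 4), cumulative = round(x$cum, 4))
  colnames(out) <- if (!is.null(x$scale)) x$scale$labels else seq_along(x$p)
  print(out)
  invisible(x)
}

#' Ordinal median and quartiles
#'
#' Summarises an item's response profile as Md (Q1; Q3) in category
#' terms.  The convention used (documented, since several exist for
#' ordinal data) is: the category reported for probability `p` is the
#' smallest category whose cumulative proportion is `>= p`.
#'
#' @param marginal A `marginal_distribution` (from [marginals()]), or a
#'   bare vector of category proportions.
#' @param scale A [response_scale()] used for labelling.
#' @return An object of class `ordinal_summary` with integer codes
#'   `q1`, `median`, `q3` and their labels.
#' @examples
#' ordinal_summary(c(0.1, 0.2, 0.3, 0.3, 0.1))
#' @export
ordinal_summary <- function(marginal, scale = icf_qualifier_scale()) {
  if (inherits(marginal, "marginal_distribution")) {
    if (!is.null(marginal$scale)) scale <- marginal$scale
    p <- marginal$p
  } else {
    p <- as.numeric(marginal)
  }
  if (length(p) != scale$m)
    stop("marginal length does not match scale")
  if (abs(sum(p) - 1) > 1e-8)
    stop("marginal proportions must sum to 1")
  cum <- cumsum(p)
  at <- function(prob) which(cum >= prob - 1e-12)[1]
  codes <- c(q1 = at(0.25), median = at(0.5), q3 = at(0.75))
  structure(list(q1 = codes[["q1"]], median = codes[["median"]],
                 q3 = codes[["q3"]],
                 labels = scale$labels[codes], scale = scale),
            class = "ordinal_summary")
}

#' @export
print.ordinal_summary <- function(x, ...) {
  cat(sprintf("Md %s (Q1 %s; Q3 %s)   [smallest category with cumulative proportion >= p]\n",
              x$labels[2], x$labels[1], x$labels[3]))
  invisible(x)
}
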