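#' @title Measures of agreement and disagreement for paired ordinal data
#' @description
#' The five measures reported per item in paired rating-scale studies:
#'
#' * `PA` — percentage agreement, the proportion of pairs on the
#'   agreement diagonal of the contingency table;
#' * `RP` — Relative Position, the systematic (group-level) shift
#'   between the two marginal distributions, `P(A < B) - P(B < A)`;
#' * `RV` — Relative rank Variance, a rank-based variance of the
#'   additional individual variability, built on augmented mean ranks;
#' * `D` — the disorder measure, the proportion of discordantly ordered
#'   subject pairs out of all `C(n,2)` pair combinations;
#' * `r_s` — the Spearman rank-order correlation (mid-ranks for ties).
#'
#' All five are rank-invariant: any order-preserving relabelling of the
#' categories leaves them unchanged.  Values are returned in full
#' floating precision; rounding to the 2 decimals conventional in report
#' tables happens only in the reporting layer ([write_results()]).
#' @name disagreement-measures
NULL

measure_ranges <- list(
  PA = c(0, 1), RP = c(-1, 1), RV = c(0, Inf), D = c(0, 1), rs = c(-1, 1))

#' Measure value with optional confidence bounds
#'
#' @param estimate Point estimate.
#' @param measure One of `"PA"`, `"RP"`, `"RV"`, `"D"`, `"rs"`.
#' @param lower,upper Optional 95 percent (or other level) bounds.
#' @param level Confidence level of the bounds, if present.
#' @param method How the bounds were obtained, if present.
#' @return An object of class `measure_value`.
#' @export
measure_value <- function(estimate, measure, lower = NA_real_, upper = NA_real_,
                          level = NA_real_, method = NULL) {
  measure <- match.arg(measure, names(measure_ranges))
  rng <- measure_ranges[[measure]]
  # RV is reported unclipped: tiny-n pathological tables can exceed 1
  # (the nominal [0,1] range is the large-n statement), so only the
  # hard lower bound 0 applies there.
  if (is.finite(estimate) &&
      (estimate < rng[1] - 1e-9 || estimate > rng[2] + 1e-9))
    stop(sprintf("%s = %.6g outside admissible range [%g, %g]",
                 measure, estimate, rng[1], rng[2]))
  structure(list(estimate = as.numeric(estimate), measure = measure,
                 lower = as.numeric(lower), upper = as.numeric(upper),
                 level = level, method = method),
            class = "measure_value")
}

#' @export
print.measure_value <- function(x, ...) {
  cat(sprintf("%s = %.4f", x$measure, x$estimate))
  if (!is.na(x$lower) || !is.na(x$upper))
    cat(sprintf("  [%g%% CI %.4f to %.4f, %s]",
                100 * x$level, x$lower, x$upper,
                if (is.null(x$method)) "?" else x$method))
  cat("\n")
  invisible(x)
}

## ---- internal fast paths on a plain count matrix --------------------------

pa_stat <- function(M) sum(diag(M)) / sum(M)

rp_stat <- function(M) {
  n <- sum(M)
  m <- nrow(M)
  p <- rowSums(M) / n            # first assessment (A)
  q <- colSums(M) / n            # second assessment (B)
  Fa <- c(0, cumsum(p)[-m])      # F^A_{j-1}
  Fb <- c(0, cumsum(q)[-m])      # F^B_{i-1}
  sum(q * Fa) - sum(p * Fb)      # P(A<B) - P(B<A), marginal-product form
}

aug_rank_stat <- function(M) {
  m <- nrow(M)
  # rx: subjects ordered by A category, ties broken by B; mean rank per cell
  rowbefore <- c(0, cumsum(rowSums(M)))[seq_len(m)]
  left <- t(apply(M, 1, function(r) c(0, cumsum(r))[seq_len(m)]))
  rx <- matrix(rowbefore, m, m) + left + (M + 1) / 2
  # ry: ordered by B, ties broken by A
  colbefore <- c(0, cumsum(colSums(M)))[seq_len(m)]
  up <- apply(M, 2, function(cl) c(0, cumsum(cl))[seq_len(m)])
  ry <- matrix(colbefore, m, m, byrow = TRUE) + up + (M + 1) / 2
  list(rx = rx, ry = ry)
}

rv_stat <- function(M) {
  n <- sum(M)
  r <- aug_rank_stat(M)
  (6 / n^3) * sum(M * (r$rx - r$ry)^2)
}

d_stat <- function(M) {
  n <- sum(M)
  if (n < 2) stop("D undefined for fewer than 2 subjects")
  m <- nrow(M)
  # discordant subject pairs: for each cell (i,j), partners strictly
  # below-and-right (k > i, l < j); each unordered pair counted once
  disc <- 0
  for (i in seq_len(m - 1)) {
    for (j in 2:m) {
      if (M[i, j] == 0) next
      disc <- disc + M[i, j] * sum(M[(i + 1):m, 1:(j - 1)])
    }
  }
  disc / choose(n, 2)
}

rs_stat <- function(a, b) {
  if (length(a) < 2) stop("Spearman correlation needs at least 2 pairs")
  ra <- rank(a); rb <- rank(b)
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0)
    stop("zero rank variance: Spearman correlation undefined for a constant assessment")
  stats::cor(ra, rb)
}

## ---- exported measures ----------------------------------------------------

#' Percentage agreement
#'
#' Proportion of pairs on the agreement diagonal, `PA = sum(n_ii) / n`.
#'
#' @param table A [contingency_table()] or [paired_assessments()].
#' @return A [measure_value()] with measure `"PA"`.
#' @examples
#' percentage_agreement(contingency_table(matrix(1, 5, 5)))  # 0.2
#' @export
percentage_agreement <- function(table) {
  measure_value(pa_stat(as_table_matrix(table)), "PA")
}

#' Relative Position (systematic disagreement)
#'
#' The difference `P(A < B) - P(B < A)` between the two marginal
#' distributions, estimated by the marginal-product convention over all
#' `n^2` cross-combinations of the two marginal samples (self-pairings
#' included).  RP ranges over `[-1, 1]` and is positive when the
#' *second* assessment source uses higher categories more often than the
#' first; it is the group-level (bias) component of disagreement,
#' separate from the individual variability measured by RV and D.
#'
#' @inheritParams percentage_agreement
#' @return A [measure_value()] with measure `"RP"`.
#' @examples
#' tab <- matrix(0, 5, 5); tab[1, 5] <- 10
#' relative_position(contingency_table(tab))  # +1: B maximally higher
#' @export
relative_position <- function(table) {
  measure_value(rp_stat(as_table_matrix(table)), "RP")
}

#' Augmented mean ranks
#'
#' The rank construction underlying RV.  Subjects are ranked 1..n
#' primarily by their first-assessment category with ties broken by the
#' second (`rx`), and symmetrically primarily by the second with ties
#' broken by the first (`ry`); subjects sharing a cell receive the mean
#' of the ranks the cell spans.  Both weighted rank totals equal
#' `n(n+1)/2` (each is a complete ranking of the n subjects), and a
#' subject's two augmented ranks coincide exactly when the paired
#' ordering carries no additional individual variability.
#'
#' @inheritParams percentage_agreement
#' @return An object of class `augmented_ranks`: list with m-by-m
#'   matrices `rx` and `ry` (mean rank per cell; cells with zero count
#'   carry the rank they would receive).
#' @examples
#' augmented_mean_ranks(contingency_table(matrix(1, 2, 2)))
#' @export
augmented_mean_ranks <- function(table) {
  r <- aug_rank_stat(as_table_matrix(table))
  structure(r, class = "augmented_ranks")
}

#' @export
print.augmented_ranks <- function(x, ...) {
  cat("Augmented mean ranks (rx: ordered by first source, ry: by second):\n")
  cat("rx:\n"); print(x$rx)
  cat("ry:\n"); print(x$ry)
  invisible(x)
}

#' Relative rank Variance (individual variability)
#'
#' `RV = (6 / n^3) * sum_ij n_ij * (rx_ij - ry_ij)^2`, with `rx`, `ry`
#' the [augmented_mean_ranks()].  RV is 0 when every subject keeps the
#' same augmented rank in both orderings (in particular for any table
#' concentrated on the agreement diagonal).  On a five-category scale
#' the uniformly filled table gives the practical maximum 0.61
#' (exactly 9600/15625 = 0.6144).  Pathological tiny-n tables can
#' exceed 1; the value is reported unclipped.
#'
#' @inheritParams percentage_agreement
#' @return A [measure_value()] with measure `"RV"`.
#' @examples
#' relative_rank_variance(contingency_table(matrix(1, 5, 5)))  # 0.6144
#' @export
relative_rank_variance <- function(table) {
  measure_value(rv_stat(as_table_matrix(table)), "RV")
}

#' Disorder measure D
#'
#' The proportion of subject pairs whose two assessments are
#' discordantly ordered — `(a_k - a_l)(b_k - b_l) < 0` — out of all
#' `C(n,2)` different pair combinations.  Pairs tied on either
#' coordinate count in the denominator but are never disordered.  For
#' example the pair (no, moderate) is disordered with (slight, slight),
#' while both agree in ordering with (moderate, major).
#'
#' @param pairs A [paired_assessments()] collection or a
#'   [contingency_table()] (the two routes agree exactly).
#' @return A [measure_value()] with measure `"D"`.
#' @examples
#' disorder_measure(paired_assessments(1:2, c(1, 2), c(3, 2)))  # 1
#' @export
disorder_measure <- function(pairs) {
  M <- as_table_matrix(pairs)
  measure_value(d_stat(M), "D")
}

#' Spearman rank-order correlation
#'
#' Product-moment correlation of mid-ranks (ties receive mean ranks).
#' Reported for inter-scale comparisons as the (weaker) association
#' counterpart to the order-consistency evaluation.
#'
#' @param pairs A [paired_assessments()] collection.
#' @return A [measure_value()] with measure `"rs"`.
#' @examples
#' spearman_rho(paired_assessments(1:3, c(1, 2, 3), c(2, 1, 3)))  # 0.5
#' @export
spearman_rho <- function(pairs) {
  if (!inherits(pairs, "paired_assessments"))
    stop("spearman_rho needs the raw paired assessments (ranks are subject-level)")
  measure_value(rs_stat(pairs$a, pairs$b), "rs")
}
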