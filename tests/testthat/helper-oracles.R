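# Independent brute-force oracles for the disagreement measures.
# These deliberately avoid the code paths they check: RP by exhaustive
# n^2 cross-pair enumeration of the marginal samples, D by enumerating
# all C(n,2) subject pairs, augmented ranks by explicitly sorting the
# subjects.  All O(n^2) or worse; used on small tables only.

tab_to_pairs_codes <- function(M) {
  # expand a count matrix into the (a, b) code vectors it tabulates
  m <- nrow(M)
  idx <- which(M > 0, arr.ind = TRUE)
  a <- rep(idx[, 1], M[idx])
  b <- rep(idx[, 2], M[idx])
  list(a = as.integer(a), b = as.integer(b))
}

oracle_rp <- function(M) {
  p <- tab_to_pairs_codes(M)
  n <- length(p$a)
  lt <- 0; gt <- 0
  for (k in seq_len(n)) {          # all n^2 cross-pairings of the marginals
    lt <- lt + sum(p$a[k] < p$b)
    gt <- gt + sum(p$b < p$a[k])
  }
  (lt - gt) / n^2
}

oracle_d <- function(a, b) {
  n <- length(a)
  disc <- 0
  for (k in seq_len(n - 1))
    for (l in (k + 1):n)
      if ((a[k] - a[l]) * (b[k] - b[l]) < 0) disc <- disc + 1
  disc / choose(n, 2)
}

oracle_aug_ranks <- function(M) {
  # rank subjects by A then B (rx) and by B then A (ry); mean per cell
  p <- tab_to_pairs_codes(M)
  n <- length(p$a)
  m <- nrow(M)
  rank_by <- function(primary, secondary) {
    ord <- order(primary, secondary)
    r <- numeric(n)
    r[ord] <- seq_len(n)
    # subjects in the same cell share the mean of their ranks
    cell <- paste(primary, secondary)
    stats::ave(r, cell, FUN = mean)
  }
  rx_s <- rank_by(p$a, p$b)
  ry_s <- rank_by(p$b, p$a)
  rx <- matrix(NA_real_, m, m); ry <- matrix(NA_real_, m, m)
  for (k in seq_len(n)) {
    rx[p$a[k], p$b[k]] <- rx_s[k]
    ry[p$a[k], p$b[k]] <- ry_s[k]
  }
  list(rx = rx, ry = ry)
}

random_table <- function(m, max_n = 50) {
  n <- sample(2:max_n, 1)
  cells <- sample.int(m * m, n, replace = TRUE)
  matrix(tabulate(cells, m * m), m, m)
}

# order-preserving relabeling: merge duplicated category boundaries is not
# allowed (must stay strictly monotone), so map codes through a strictly
# increasing random map into a wider scale
relabel_table <- function(M, m_out) {
  m <- nrow(M)
  map <- sort(sample.int(m_out, m))
  out <- matrix(0, m_out, m_out)
  for (i in seq_len(m)) for (j in seq_len(m))
    out[map[i], map[j]] <- out[map[i], map[j]] + M[i, j]
  out
}

uniform_table <- function(m, c = 1) contingency_table(matrix(c, m, m))

make_pairs <- function(a, b, m = max(a, b, 5)) {
  paired_assessments(seq_along(a), a, b,
                     scale = response_scale(as.character(seq_len(m))))
}
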