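test_that("percentage agreement matches the diagonal proportion", {
  diag_tab <- contingency_table(diag(c(3, 1, 4, 1, 5)))
  expect_equal(percentage_agreement(diag_tab)$estimate, 1)
  expect_equal(percentage_agreement(uniform_table(5))$estimate, 0.2)
  M <- matrix(0, 5, 5); M[1, 4] <- 7
  expect_equal(percentage_agreement(contingency_table(M))$estimate, 0)
})

test_that("relative position: extremes, identity and a hand-enumerated case", {
  M <- matrix(0, 5, 5); M[1, 5] <- 12
  expect_equal(relative_position(contingency_table(M))$estimate, 1)
  expect_equal(relative_position(contingency_table(t(M)))$estimate, -1)

  one <- matrix(0, 5, 5); one[3, 3] <- 9
  expect_equal(relative_position(contingency_table(one))$estimate, 0)

  # {(1,2),(1,2),(2,2)}: P(A<B) = 6/9, P(B<A) = 0
  rp <- relative_position(contingency_from_pairs(make_pairs(c(1, 1, 2), c(2, 2, 2))))
  expect_equal(rp$estimate, 2 / 3, tolerance = 1e-12)
})

test_that("augmented mean ranks: single subject, 2x2 hand case, rank totals", {
  M1 <- matrix(0, 5, 5); M1[1, 1] <- 1
  r1 <- augmented_mean_ranks(contingency_table(M1))
  expect_equal(r1$rx[1, 1], 1)
  expect_equal(r1$ry[1, 1], 1)

  r2 <- augmented_mean_ranks(uniform_table(2))
  expect_equal(r2$rx, matrix(c(1, 3, 2, 4), 2), ignore_attr = TRUE)
  expect_equal(r2$ry, matrix(c(1, 2, 3, 4), 2), ignore_attr = TRUE)

  set.seed(5)
  for (m in 2:6) {
    M <- random_table(m)
    n <- sum(M)
    r <- augmented_mean_ranks(contingency_table(M))
    expect_equal(sum(M * r$rx), n * (n + 1) / 2)
    expect_equal(sum(M * r$ry), n * (n + 1) / 2)
    expect_true(all(r$rx[M > 0] >= 1 & r$rx[M > 0] <= n))
    expect_true(all(r$ry[M > 0] >= 1 & r$ry[M > 0] <= n))
  }
})

test_that("relative rank variance: uniform maximum, diagonal floor, 2x2 case", {
  expect_equal(relative_rank_variance(uniform_table(5))$estimate, 9600 / 15625)
  expect_equal(round(relative_rank_variance(uniform_table(5))$estimate, 2), 0.61)
  expect_equal(relative_rank_variance(uniform_table(2))$estimate, 0.1875)
  set.seed(13)
  for (rep in 1:5) {
    d <- diag(sample.int(6, 5, replace = TRUE))
    expect_equal(relative_rank_variance(contingency_table(d))$estimate, 0)
  }
})

test_that("closed-form RV for uniform m x m tables, any per-cell count", {
  closed <- function(m) {
    S <- sum(outer(1:m, 1:m, function(i, j) (i - j)^2))
    6 * (m - 1)^2 * S / m^6
  }
  for (m in 2:6)
    for (cc in c(1, 3, 10))
      expect_equal(relative_rank_variance(uniform_table(m, cc))$estimate,
                   closed(m), tolerance = 1e-12,
                   label = sprintf("uniform m=%d c=%d", m, cc))
  expect_equal(closed(2), 0.1875)
  expect_equal(closed(5), 0.6144)
})

test_that("disorder measure: worked examples and error path", {
  expect_equal(disorder_measure(make_pairs(c(1, 2), c(3, 2)))$estimate, 1)
  expect_equal(disorder_measure(make_pairs(c(1, 3), c(3, 4)))$estimate, 0)
  expect_equal(disorder_measure(make_pairs(c(1, 2, 3), c(3, 2, 4)))$estimate,
               1 / 3, tolerance = 1e-12)
  M <- matrix(0, 5, 5); M[2, 4] <- 1
  expect_error(disorder_measure(contingency_table(M)), "fewer than 2")
})

test_that("spearman rho: monotone, reversal, classic no-tie case, degenerate", {
  expect_equal(spearman_rho(make_pairs(1:3, 1:3))$estimate, 1)
  expect_equal(spearman_rho(make_pairs(1:3, 3:1))$estimate, -1)
  expect_equal(spearman_rho(make_pairs(c(1, 2, 3), c(2, 1, 3)))$estimate, 0.5)
  expect_error(spearman_rho(make_pairs(c(1, 2, 3), c(2, 2, 2))),
               "zero rank variance")
})

test_that("oracle equivalence on random tables: RP, D, augmented ranks", {
  set.seed(2026)
  for (rep in 1:60) {
    m <- sample(2:6, 1)
    M <- random_table(m)
    tab <- contingency_table(M)
    expect_equal(relative_position(tab)$estimate, oracle_rp(M),
                 tolerance = 1e-12)
    codes <- tab_to_pairs_codes(M)
    if (sum(M) >= 2)
      expect_identical(disorder_measure(tab)$estimate,
                       oracle_d(codes$a, codes$b))
    r <- augmented_mean_ranks(tab)
    ro <- oracle_aug_ranks(M)
    occ <- M > 0
    expect_equal(r$rx[occ], ro$rx[occ], tolerance = 1e-12)
    expect_equal(r$ry[occ], ro$ry[occ], tolerance = 1e-12)
  }
})

test_that("transpose symmetry: RP antisymmetric; PA, RV, D symmetric", {
  set.seed(99)
  for (rep in 1:40) {
    M <- random_table(sample(2:6, 1))
    tab <- contingency_table(M)
    tt <- contingency_table(t(M))
    expect_equal(relative_position(tt)$estimate,
                 -relative_position(tab)$estimate, tolerance = 1e-12)
    expect_equal(percentage_agreement(tt)$estimate,
                 percentage_agreement(tab)$estimate)
    expect_equal(relative_rank_variance(tt)$estimate,
                 relative_rank_variance(tab)$estimate, tolerance = 1e-12)
    if (sum(M) >= 2)
      expect_equal(disorder_measure(tt)$estimate,
                   disorder_measure(tab)$estimate, tolerance = 1e-12)
  }
})

test_that("all measures are rank-invariant under order-preserving relabeling", {
  set.seed(321)
  for (rep in 1:25) {
    m <- sample(2:5, 1)
    M <- random_table(m)
    Mr <- relabel_table(M, m + sample(1:4, 1))
    tab <- contingency_table(M); tabr <- contingency_table(Mr)
    expect_equal(percentage_agreement(tabr)$estimate,
                 percentage_agreement(tab)$estimate)
    expect_equal(relative_position(tabr)$estimate,
                 relative_position(tab)$estimate, tolerance = 1e-12)
    expect_equal(relative_rank_variance(tabr)$estimate,
                 relative_rank_variance(tab)$estimate, tolerance = 1e-12)
    if (sum(M) >= 2) {
      expect_equal(disorder_measure(tabr)$estimate,
                   disorder_measure(tab)$estimate, tolerance = 1e-12)
      co <- tab_to_pairs_codes(M); cr <- tab_to_pairs_codes(Mr)
      if (length(unique(co$a)) > 1 && length(unique(co$b)) > 1)
        expect_equal(rs <- spearman_rho(make_pairs(cr$a, cr$b, nrow(Mr)))$estimate,
                     spearman_rho(make_pairs(co$a, co$b, m))$estimate,
                     tolerance = 1e-12)
    }
  }
})

test_that("perfect agreement forces RP = RV = D = 0", {
  set.seed(55)
  for (rep in 1:10) {
    d <- diag(sample.int(8, 5, replace = TRUE))
    tab <- contingency_table(d)
    expect_equal(percentage_agreement(tab)$estimate, 1)
    expect_equal(relative_position(tab)$estimate, 0)
    expect_equal(relative_rank_variance(tab)$estimate, 0)
    expect_equal(disorder_measure(tab)$estimate, 0)
  }
})

test_that("measure_value enforces admissible ranges; RV stays unclipped above 1", {
  expect_error(measure_value(1.2, "PA"), "outside admissible range")
  expect_error(measure_value(-1.5, "RP"), "outside admissible range")
  # n = 2 full reversal: pathological small-n table exceeds the nominal cap
  M <- matrix(0, 2, 2); M[1, 2] <- 1; M[2, 1] <- 1
  expect_equal(relative_rank_variance(contingency_table(M))$estimate, 1.5)
})
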