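test_that("rater_model and study_design validate parameters", {
  expect_error(rater_model(noise = -1), ">= 0")
  expect_error(rater_model(thresholds = c(1, 1, 2)), "strictly increasing")
  expect_error(study_design(n_subjects = 1), ">= 2")
  expect_error(study_design(completion = 0), "\\(0, 1\\]")
  expect_error(study_design(items = c("x", "x")), "distinct")
})

test_that("zero noise, equal bias and shared thresholds give PA = 1 exactly", {
  m0 <- rater_model(bias = 0.2, noise = 0)
  pa <- generate_paired_assessments(m0, m0, 100, seed = 4)
  expect_equal(percentage_agreement(pa)$estimate, 1)
})

test_that("generation is deterministic given seed", {
  ma <- rater_model(0, 0.4); mb <- rater_model(0.5, 0.4)
  p1 <- generate_paired_assessments(ma, mb, 60, seed = 10)
  p2 <- generate_paired_assessments(ma, mb, 60, seed = 10)
  expect_identical(p1, p2)
  p3 <- generate_paired_assessments(ma, mb, 60, seed = 11)
  expect_false(identical(p1, p3))

  des <- study_design(n_subjects = 30, items = c("a", "b"), seed = 9,
                      observer_sd = 0.3, completion = 0.9)
  s1 <- generate_study(des, ma, mb)
  s2 <- generate_study(des, ma, mb)
  expect_identical(s1, s2)
})

test_that("an extreme positive bias pushes b to the top category; RP matches its oracle", {
  ma <- rater_model(0, 0.3); mb <- rater_model(10, 0.3)
  pa <- generate_paired_assessments(ma, mb, 500, seed = 6)
  expect_true(all(pa$b == 5))
  tab <- contingency_from_pairs(pa)
  rp <- relative_position(tab)$estimate
  expect_equal(rp, oracle_rp(as.matrix(unclass(tab))), tolerance = 1e-12)
  expect_gt(rp, 0.5)
})

test_that("completion probability 1 yields full per-item n; missingness is binomial-ish", {
  ma <- rater_model(0, 0.3); mb <- rater_model(0.2, 0.3)
  full <- generate_study(study_design(n_subjects = 40, items = c("i1", "i2"),
                                      completion = 1, seed = 2), ma, mb)
  expect_false(anyNA(full$response_a) || anyNA(full$response_b))
  expect_equal(nrow(full), 80)

  # completion 0.95, 12 items x 89 subjects: complete-n concentrated near 84.5
  des <- study_design(n_subjects = 89, completion = 0.95, seed = 31)
  st <- generate_study(des, ma, mb)
  ncomp <- tapply(!is.na(st$response_a) & !is.na(st$response_b),
                  st$item_id, sum)
  expect_true(all(ncomp >= stats::qbinom(0.0005, 89, 0.95) & ncomp <= 89))
  expect_gt(mean(ncomp), 89 * 0.95 - 3)
  expect_lt(mean(ncomp), 89 * 0.95 + 3)
})

test_that("observer_sd = 0 reduces exactly to generate_paired_assessments per item", {
  ma <- rater_model(0.1, 0.25); mb <- rater_model(0.4, 0.35)
  des <- study_design(n_subjects = 25, items = c("walk", "sleep"),
                      item_offsets = c(walk = 0.2, sleep = -0.1),
                      n_observers = 11, observer_sd = 0, completion = 1,
                      seed = 17)
  st <- generate_study(des, ma, mb)
  theta <- withr::with_seed(substream_seed(17, "subjects"), stats::rnorm(25))
  for (item in des$items) {
    ref <- generate_paired_assessments(
      ma, mb, 25, seed = substream_seed(17, paste0("item-", item)),
      theta = theta + des$item_offsets[[item]])
    got <- st[st$item_id == item, ]
    expect_equal(got$response_a, ref$a, label = item)
    expect_equal(got$response_b, ref$b, label = item)
  }
})

test_that("bias difference drives the sign of RP (parameter recovery, reduced)", {
  mean_rp <- function(bias_b, seeds, n = 500) {
    mean(vapply(seeds, function(s) {
      pa <- generate_paired_assessments(rater_model(0, 0.3),
                                        rater_model(bias_b, 0.3), n, seed = s)
      relative_position(contingency_from_pairs(pa))$estimate
    }, numeric(1)))
  }
  seeds <- 1:8
  expect_lt(mean_rp(-0.5, seeds), -0.05)
  expect_lt(abs(mean_rp(0, seeds)), 0.05)
  expect_gt(mean_rp(0.5, seeds), 0.05)
})

test_that("source noise drives RV and D upward (reduced sweep)", {
  avg <- function(sigma, seeds, n = 400) {
    vals <- vapply(seeds, function(s) {
      pa <- generate_paired_assessments(rater_model(0, sigma),
                                        rater_model(0, sigma), n, seed = s)
      tab <- contingency_from_pairs(pa)
      c(relative_rank_variance(tab)$estimate, disorder_measure(tab)$estimate)
    }, numeric(2))
    rowMeans(vals)
  }
  seeds <- 1:8
  v1 <- avg(0.1, seeds); v2 <- avg(0.5, seeds); v3 <- avg(1.5, seeds)
  expect_lt(v1[1], v2[1]); expect_lt(v2[1], v3[1])  # RV increasing
  expect_lt(v1[2], v2[2]); expect_lt(v2[2], v3[2])  # D increasing
})

test_that("observer heterogeneity widens per-item RP dispersion, not its sign", {
  per_item_rp <- function(omega, seed) {
    des <- study_design(n_subjects = 60, items = sprintf("i%02d", 1:10),
                        n_observers = 11, observer_sd = omega,
                        completion = 1, seed = seed)
    st <- generate_study(des, rater_model(0, 0.3), rater_model(0.5, 0.3))
    vapply(split(st, st$item_id), function(d) {
      relative_position(contingency_from_pairs(
        paired_assessments(d$subject_id, d$response_a, d$response_b)))$estimate
    }, numeric(1))
  }
  # within one study all items share the realized observer pool, so the
  # heterogeneity shows up as dispersion of per-item RP estimates pooled
  # over replicate studies
  lo <- unlist(lapply(1:6, function(s) per_item_rp(0, s)))
  hi <- unlist(lapply(1:6, function(s) per_item_rp(1.0, s)))
  expect_gt(stats::sd(hi), stats::sd(lo))
  expect_gt(mean(hi), 0)  # expected sign of RP unchanged
})
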