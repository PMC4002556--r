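#' Resampling plan for confidence intervals
#'
#' @param method `"bootstrap"` (percentile, subject-level, the default)
#'   or `"jackknife"` (leave-one-out pseudo-values with a normal
#'   approximation, useful as a cross-check).
#' @param B Number of bootstrap replicates (>= 100); default 2000.
#' @param level Confidence level in (0.5, 1); default 0.95.
#' @param seed Integer seed, required for the bootstrap.  The seed is an
#'   explicit argument: no hidden global RNG state enters a report.
#' @return An object of class `resampling_plan`.
#' @export
resampling_plan <- function(method = c("bootstrap", "jackknife"),
                            B = 2000L, level = 0.95, seed = NULL) {
  method <- match.arg(method)
  if (!is.numeric(level) || level <= 0.5 || level >= 1)
    stop("confidence level must lie in (0.5, 1)")
  if (method == "bootstrap") {
    if (!is.numeric(B) || B < 100)
      stop("bootstrap needs B >= 100 replicates")
    if (is.null(seed) || is.na(suppressWarnings(as.integer(seed))))
      stop("bootstrap needs an explicit integer seed")
    seed <- as.integer(seed)
  }
  structure(list(method = method, B = as.integer(B), level = level, seed = seed),
            class = "resampling_plan")
}

# statistic dispatcher on raw code vectors, used by resampling
stat_fun <- function(measure, m) {
  switch(measure,
    PA = function(a, b) pa_stat(codes_to_matrix(a, b, m)),
    RP = function(a, b) rp_stat(codes_to_matrix(a, b, m)),
    RV = function(a, b) rv_stat(codes_to_matrix(a, b, m)),
    D  = function(a, b) d_stat(codes_to_matrix(a, b, m)),
    rs = function(a, b) rs_stat(a, b),
    stop("unknown measure: ", measure))
}

codes_to_matrix <- function(a, b, m) {
  matrix(tabulate((a - 1L) * m + b, nbins = m * m), m, m, byrow = TRUE)
}

clip_bounds <- function(lo, hi, measure) {
  rng <- measure_ranges[[measure]]
  c(max(lo, rng[1]), min(hi, rng[2]))
}

#' Resampling confidence interval for a disagreement measure
#'
#' Subject-level resampling: the pair (a, b) of each subject is the
#' sampling unit, so the dependence between the two assessments is
#' preserved.  The percentile bootstrap resamples the n subjects with
#' replacement `B` times and takes the empirical quantiles of the
#' recomputed measure; the jackknife builds leave-one-out pseudo-values
#' and a normal-approximation interval.  Bounds are clipped to the
#' measure's admissible range and the result is deterministic given
#' (data, plan, seed).
#'
#' @param pairs A [paired_assessments()] collection (n >= 2).
#' @param measure One of `"PA"`, `"RP"`, `"RV"`, `"D"`, `"rs"`.
#' @param plan A [resampling_plan()].
#' @return A [measure_value()] with bounds attached.
#' @examples
#' pa <- paired_assessments(1:6, c(1, 2, 2, 3, 4, 5), c(2, 2, 3, 4, 4, 5))
#' resample_ci(pa, "RP", resampling_plan(B = 200, seed = 1))
#' @export
resample_ci <- function(pairs, measure = c("PA", "RP", "RV", "D", "rs"),
                        plan = resampling_plan(seed = stop("seed required"))) {
  measure <- match.arg(measure)
  if (!inherits(pairs, "paired_assessments"))
    stop("resample_ci needs a paired_assessments collection")
  n <- nrow(pairs)
  if (n < 2) stop("resampling needs at least 2 subjects")
  m <- attr(pairs, "scale")$m
  # canonical subject order: the interval must depend only on the
  # multiset of pairs, not on row order
  ord <- order(pairs$a, pairs$b)
  a <- pairs$a[ord]; b <- pairs$b[ord]
  f <- stat_fun(measure, m)
  est <- f(a, b)
  alpha <- 1 - plan$level

  if (plan$method == "bootstrap") {
    stats_b <- withr_seed(plan$seed, {
      vapply(seq_len(plan$B), function(r) {
        ii <- sample.int(n, n, replace = TRUE)
        tryCatch(f(a[ii], b[ii]), error = function(e) NA_real_)
      }, numeric(1))
    })
    bad <- mean(is.na(stats_b))
    if (bad > 0.5)
      stop(sprintf("measure %s undefined on %.0f%% of bootstrap replicates (degenerate data)",
                   measure, 100 * bad))
    qs <- stats::quantile(stats_b, c(alpha / 2, 1 - alpha / 2),
                          na.rm = TRUE, names = FALSE)
  } else {
    loo <- vapply(seq_len(n), function(i) {
      tryCatch(f(a[-i], b[-i]), error = function(e) NA_real_)
    }, numeric(1))
    bad <- mean(is.na(loo))
    if (bad > 0.5)
      stop(sprintf("measure %s undefined on %.0f%% of jackknife replicates (degenerate data)",
                   measure, 100 * bad))
    pv <- n * est - (n - 1) * loo
    pv <- pv[!is.na(pv)]
    se <- stats::sd(pv) / sqrt(length(pv))
    z <- stats::qnorm(1 - alpha / 2)
    qs <- mean(pv) + c(-1, 1) * z * se
  }
  bounds <- clip_bounds(qs[1], qs[2], measure)
  measure_value(est, measure, lower = bounds[1], upper = bounds[2],
                level = plan$level, method = plan$method)
}

# run expr under a temporary RNG state so library code never disturbs
# the caller's stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Does an interval show a significant shift?
#'
#' TRUE when the confidence interval excludes 0; an endpoint exactly at
#' 0 is treated as *not* excluding it (conservative boundary rule).
#' Used to flag significant non-zero RP values, i.e. evidence of
#' systematic disagreement in the population of assessments.
#'
#' @param value A [measure_value()] with bounds present.
#' @return Logical flag.
#' @examples
#' significant_shift(measure_value(0.37, "RP", lower = 0.27, upper = 0.46))
#' @export
significant_shift <- function(value) {
  if (!inherits(value, "measure_value"))
    stop("expected a measure_value")
  if (is.na(value$lower) || is.na(value$upper))
    stop("significance flag needs confidence bounds")
  isTRUE(value$lower > 0 || value$upper < 0)
}
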