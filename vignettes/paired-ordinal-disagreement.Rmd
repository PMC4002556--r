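---
title: "Decomposing disagreement in paired ordinal assessments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing disagreement in paired ordinal assessments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordagree)
```

## The model and its assumptions

`ordagree` analyses paired assessments on an ordered `m`-category scale
(default: the five-point problem qualifier *no < slight < moderate <
major < total*). The data object is the square contingency table of
pair frequencies `n_ij`, `i` indexing the first source's category and
`j` the second's. Nothing metric is assumed about the categories:
every statistic in the package is invariant under order-preserving
relabelling, which is the property that licenses using it on rating
scales at all.

Observed disagreement is decomposed into two components with different
substantive meanings:

* **Systematic disagreement** (bias) is a property of the *group*: the
  two marginal distributions differ in position. It is measured by the
  Relative Position `RP = P(A < B) − P(B < A)`. If one source were
  simply "stricter", subjects would keep their relative ordering while
  the whole distribution shifts; RP captures exactly that shift and
  nothing else.
* **Individual variability** (noise) is a property of *pairs*: subjects
  change their relative order between the two assessments. It is
  measured by the Relative rank Variance `RV` and the disorder measure
  `D`. High RV/D with near-zero RP means the sources scatter without a
  common direction — a different problem requiring a different remedy
  than bias.

Percentage agreement `PA` alone cannot distinguish these: two item
comparisons can share `PA = 43%` with one driven by bias and the other
by noise. That distinction is the reason this suite exists.

### Augmented mean ranks and RV

`RV` is built on *augmented mean ranks*: rank the `n` subjects by their
first-source category, breaking ties by the second source, giving each
cell's subjects the mean of the ranks the cell spans
(`Rx_ij = Σ_{k<i} n_k· + Σ_{l<j} n_il + (n_ij + 1)/2`); symmetrically
rank by the second source tie-broken by the first (`Ry`). Both are
complete rankings — each weighted total is `n(n+1)/2` — and

```
RV = (6 / n³) · Σ_ij n_ij (Rx_ij − Ry_ij)².
```

When each subject holds the same rank in both orderings (all mass on
the agreement diagonal, or any purely monotone pattern), `RV = 0`. For
a uniformly filled `m × m` table the value has the closed form
`6 (m−1)² S(m) / m⁶` with `S(m) = Σ_{i,j} (i−j)²`, which gives 0.1875
at `m = 2` and `9600/15625 = 0.6144 ≈ 0.61` at `m = 5` — the practical
maximum for a five-category scale:

```{r}
relative_rank_variance(contingency_table(matrix(1, 5, 5)))
```

## Numerical conventions (deliberate choices)

Where the method literature leaves room, the package fixes one
convention and states it; these were design decisions, made once:

* **RP estimator.** RP is defined at the probability level; we estimate
  `P(A < B)` and `P(B < A)` by the marginal-product over all `n²`
  cross-combinations of the two marginal samples, self-pairings
  included (`P̂(A<B) = Σ_j q_j F^A_{j−1}`). An `n(n−1)` convention
  excluding self-pairings exists; the difference is `O(1/n)` and
  vanishes at study sizes. The product form is exactly checkable
  against brute-force enumeration, which the test suite does on
  hundreds of random tables.
* **D denominator.** `D` divides the number of discordantly ordered
  subject pairs by *all* `C(n,2)` pair combinations; ties on either
  coordinate stay in the denominator and never count as disordered.
* **RV range.** RV is reported unclipped. Its nominal range is
  `[0, 1]`, but that is the large-`n` statement: degenerate tiny-`n`
  tables exceed it (the `n = 2` full reversal gives 1.5). Clipping
  would hide a diagnostic signal.
* **Ordinal median/quartiles.** `ordinal_summary()` reports, for
  `p ∈ {0.25, 0.5, 0.75}`, the smallest category whose cumulative
  proportion is `≥ p`. No single convention is standard for ordinal
  data; this is the simplest order-statistic rule and every output
  labels it.
* **Orientation.** RP's sign depends on which source counts as
  "second". `study_config()` makes the convention explicit per study
  mode — inter-scale: positive RP = second questionnaire (`response_b`)
  higher; patient-observer: positive RP = patient (`response_a`)
  higher — and every report prints the convention in force. Flipping
  orientation negates RP and changes nothing else.
* **Rounding.** All computation is full precision; the 2-decimal /
  whole-percent rounding conventional in report tables happens only in
  `write_results()`.
* **Degenerate input.** Items with fewer than 2 complete pairs become
  structured skip records rather than aborting a study; a constant
  assessment column makes `r_s` undefined (flagged, not fatal);
  `D` errors below `n = 2`.

## Confidence intervals

The original software behind published applications of this method does
not document its CI construction, so the package takes the
assumption-light route: a **subject-level percentile bootstrap**
(default `B = 2000`, level 0.95), resampling whole pairs so the
dependence between the two assessments is preserved, with a
leave-one-out **jackknife** (pseudo-value normal approximation) as a
cross-check. Consequences of this choice:

* the seed is a *required explicit argument* — identical data, plan and
  seed give byte-identical reports, and the interval is invariant to
  subject order (resampling happens on a canonically sorted copy);
* bounds are clipped to the measure's admissible range;
* published intervals computed by other software may differ slightly
  even on identical data.

`significant_shift()` flags an interval that excludes 0, with the
conservative boundary rule that an endpoint exactly at 0 is *not*
significant. Under the zero-bias generator the 95% RP interval covers 0
at its nominal rate (checked by simulation in the acceptance suite,
500 repetitions at `n = 100`, `B = 500`).

## What the generator emulates — and what it does not

`generate_paired_assessments()` operationalises the two disagreement
sources with a latent-trait model: subject severity `θ ~ N(0, 1)`;
source `s` observes `θ + β_s + ε`, `ε ~ N(0, σ_s²)`, and cuts it at its
thresholds. Parameters, all on the latent (standard-deviation) scale:

| parameter | meaning | default | why |
|---|---|---|---|
| `bias` (β) | systematic shift of a source | 0 | bias is the experimental knob |
| `noise` (σ) | source-specific perception error SD | 0.3 | moderate noise: keeps PA in the realistic 30–60% band |
| `thresholds` (τ) | category cut points | −1.5, −0.5, 0.5, 1.5 | equally spaced; all five categories occupied under a standard-normal trait |
| `observer_sd` (ω) | SD of per-observer personal bias | 0 | heterogeneity only in patient-observer scenarios |
| `completion` | per-(subject, item) completion probability | 0.95 | a few percent item-wise missingness, as real questionnaire data show |

`generate_study()` layers a study design on top: subjects share one
latent trait across items, items shift it by a difficulty offset, each
subject is examined by exactly one observer whose personal bias is
`N(β_b, ω²)`, and missingness blanks one response of a record
independently per (subject, item). A single master seed drives named
substreams (subjects / observer pool / each item), so changing one
design field does not reshuffle unrelated draws; with `ω = 0` the study
reduces exactly, stream for stream, to `generate_paired_assessments()`
per item.

The generator's purpose is to make every pipeline stage testable and to
explore power — it is *not* a fitted model of any real data set.
Features of real questionnaire data it does not emulate: non-normal and
multimodal severity distributions, item-specific threshold shapes,
within-subject response styles (end-category aversion), informative
missingness, and correlated item-specific errors. Because the observer
pool is shared by all items of a study, observer heterogeneity inflates
the dispersion of per-item RP estimates *across replicate studies*
rather than across items within one study. A green simulation-based
test therefore establishes that the estimators track their targets
under the stated model — not that any particular clinical data set
satisfies that model.

## Known limitations

* RP, RV and D are estimated without small-sample bias correction; at
  `n < 20` intervals are wide and the percentile bootstrap can be
  erratic (the method literature recommends ≥ 20 pairs).
* The jackknife interval uses a normal approximation and can undercover
  for measures bounded at the realised value (e.g. RV near 0).
* No analytic standard errors are provided; bootstrap cost grows
  linearly in `B × n_items`.
* The Relative Concentration measure from the broader rank-invariant
  family is out of scope, as are weighted kappa and polychoric
  alternatives.
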