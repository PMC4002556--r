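#' Latent-trait rater model
#'
#' One assessment source observes a subject's latent severity `theta`
#' through its own lens: it sees `theta + bias + noise` and cuts the
#' result into the m ordered categories at its thresholds.  A non-zero
#' bias difference between two sources produces systematic disagreement
#' (non-zero RP); source noise produces additional individual
#' variability (RV, D).
#'
#' @param bias Latent-scale shift of this source (default 0).
#' @param noise Latent-scale standard deviation of the source's own
#'   perception error (>= 0; default 0.3).
#' @param thresholds Strictly increasing cut points; the default
#'   `c(-1.5, -0.5, 0.5, 1.5)` spreads a standard-normal trait over all
#'   five categories of the default scale.
#' @return An object of class `rater_model`.
#' @export
rater_model <- function(bias = 0, noise = 0.3,
                        thresholds = c(-1.5, -0.5, 0.5, 1.5)) {
  if (!is.numeric(noise) || noise < 0) stop("noise must be >= 0")
  if (length(thresholds) < 1 || is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  structure(list(bias = bias, noise = noise, thresholds = thresholds),
            class = "rater_model")
}

categorize <- function(x, thresholds) findInterval(x, thresholds) + 1L

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Hierarchical seeding: each component of a simulated study (subject
#' traits, observer pool, each item) draws from its own stream seeded by
#' `substream_seed(seed, label)`, so changing one design field never
#' silently reshuffles unrelated draws.
#'
#' @param seed Master integer seed.
#' @param label Character tag of the stream.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}

#' Generate paired ordinal assessments from two rater models
#'
#' Per subject k a latent severity `theta_k ~ N(0,1)` is drawn; each
#' source s observes `theta_k + bias_s + eps_ks`, `eps_ks ~ N(0,
#' noise_s^2)`, and categorises it by its own thresholds.  Deterministic
#' given the seed.
#'
#' @param model_a,model_b [rater_model()]s for the first and second
#'   source (both must imply the same number of categories).
#' @param n Number of subjects (>= 2).
#' @param seed Integer seed.
#' @param theta Optional pre-drawn latent traits (length n); when given,
#'   the seed governs only the two noise draws.  Used by
#'   [generate_study()] so all items share the same subjects.
#' @param scale Optional [response_scale()]; default is the
#'   [icf_qualifier_scale()] when the thresholds imply m = 5.
#' @return A [paired_assessments()] collection of n subjects.
#' @examples
#' generate_paired_assessments(rater_model(), rater_model(bias = 0.5), 10, seed = 1)
#' @export
generate_paired_assessments <- function(model_a, model_b, n, seed,
                                        theta = NULL, scale = NULL) {
  stopifnot(inherits(model_a, "rater_model"), inherits(model_b, "rater_model"))
  if (n < 2) stop("need n >= 2 subjects")
  ma <- length(model_a$thresholds) + 1L
  if (length(model_b$thresholds) + 1L != ma)
    stop("the two rater models must share the number of categories")
  if (is.null(scale))
    scale <- if (ma == 5L) icf_qualifier_scale()
             else response_scale(as.character(seq_len(ma)))
  withr_seed(seed, {
    if (is.null(theta)) theta <- stats::rnorm(n)
    if (length(theta) != n) stop("theta must have length n")
    xa <- theta + model_a$bias + stats::rnorm(n, 0, model_a$noise)
    xb <- theta + model_b$bias + stats::rnorm(n, 0, model_b$noise)
    paired_assessments(sprintf("S%04d", seq_len(n)),
                       categorize(xa, model_a$thresholds),
                       categorize(xb, model_b$thresholds),
                       scale = scale)
  })
}

#' Study design for a simulated paired-assessment study
#'
#' Emulates the two designs the measures are used for: an inter-scale
#' comparison (one respondent, two questionnaires) and a
#' patient-observer comparison (self-report vs a professional drawn
#' from a small observer pool).  Defaults mirror a typical validation
#' study: 89 subjects, 12 items, a few percent item-wise missingness.
#'
#' @param n_subjects Number of subjects (>= 2); default 89.
#' @param items Character vector of item identifiers; default
#'   `"item01".."item12"`.
#' @param item_offsets Per-item difficulty offsets added to the latent
#'   trait (recycled/named; default 0).
#' @param n_observers Size of the observer pool assessing source b; each
#'   subject is examined by exactly one observer.  Default 11.  Set
#'   `observer_sd = 0` (or `n_observers = 1`) for a plain two-source
#'   design.
#' @param observer_sd Standard deviation (omega) of the per-observer
#'   personal bias around `model_b$bias`; default 0.
#' @param completion Per-(subject, item) completion probability in
#'   (0, 1]; default 0.95.  An incomplete record keeps its row with one
#'   response blanked, matching real questionnaire data.
#' @param seed Master integer seed.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_subjects = 89L,
                         items = sprintf("item%02d", 1:12),
                         item_offsets = 0,
                         n_observers = 11L,
                         observer_sd = 0,
                         completion = 0.95,
                         seed = 1L) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (completion <= 0 || completion > 1) stop("completion probability must be in (0, 1]")
  if (observer_sd < 0) stop("observer_sd must be >= 0")
  if (n_observers < 1) stop("n_observers must be >= 1")
  items <- as.character(items)
  if (anyDuplicated(items)) stop("item identifiers must be distinct")
  offs <- rep_len(item_offsets, length(items))
  if (!is.null(names(item_offsets)))
    offs <- ifelse(items %in% names(item_offsets),
                   item_offsets[items], 0)
  names(offs) <- items
  structure(list(n_subjects = as.integer(n_subjects), items = items,
                 item_offsets = offs, n_observers = as.integer(n_observers),
                 observer_sd = observer_sd, completion = completion,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Simulate a full paired-assessment study in long format
#'
#' One record per (subject, item).  Subjects share one latent trait
#' across items; each item shifts it by its difficulty offset.  In
#' patient-observer mode (`observer_sd > 0`) each subject is examined by
#' one observer whose personal bias is drawn `N(model_b$bias,
#' observer_sd^2)`; with `observer_sd = 0` the study reduces exactly,
#' stream for stream, to [generate_paired_assessments()] per item.
#' Missingness blanks one response of a record independently per
#' (subject, item) with probability `1 - completion`.
#'
#' @param design A [study_design()].
#' @param model_a,model_b [rater_model()]s for the two sources.
#' @param scale Optional [response_scale()].
#' @return A `study_data` data frame with columns `subject_id`,
#'   `item_id`, `response_a`, `response_b` (integer codes, NA = missing)
#'   and attributes `scale` and `observers` (per-subject observer id).
#' @export
generate_study <- function(design, model_a, model_b, scale = NULL) {
  stopifnot(inherits(design, "study_design"))
  m <- length(model_a$thresholds) + 1L
  if (is.null(scale))
    scale <- if (m == 5L) icf_qualifier_scale()
             else response_scale(as.character(seq_len(m)))
  n <- design$n_subjects
  subj <- sprintf("S%04d", seq_len(n))

  theta <- withr_seed(substream_seed(design$seed, "subjects"),
                      stats::rnorm(n))
  obs_assign <- withr_seed(substream_seed(design$seed, "observer-assignment"),
                           sample.int(design$n_observers, n, replace = TRUE))
  obs_bias <- withr_seed(substream_seed(design$seed, "observer-pool"),
                         stats::rnorm(design$n_observers, model_b$bias,
                                      design$observer_sd))

  recs <- lapply(design$items, function(item) {
    off <- design$item_offsets[[item]]
    sub_seed <- substream_seed(design$seed, paste0("item-", item))
    withr_seed(sub_seed, {
      xa <- theta + off + model_a$bias + stats::rnorm(n, 0, model_a$noise)
      # observer replaces the source-b bias with their personal one
      xb <- theta + off + obs_bias[obs_assign] + stats::rnorm(n, 0, model_b$noise)
      a <- categorize(xa, model_a$thresholds)
      b <- categorize(xb, model_b$thresholds)
      miss <- stats::runif(n) > design$completion
      side <- stats::runif(n) < 0.5
      a[miss & side] <- NA_integer_
      b[miss & !side] <- NA_integer_
      data.frame(subject_id = subj, item_id = item,
                 response_a = a, response_b = b,
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "scale") <- scale
  attr(out, "observers") <- stats::setNames(obs_assign, subj)
  class(out) <- c("study_data", "data.frame")
  out
}

#' Write a simulated (or any) study table to CSV
#'
#' Plain UTF-8 CSV with header `subject_id,item_id,response_a,response_b`
#' and blank cells for missing responses — the same format
#' [read_study_csv()] reads back.
#'
#' @param study A `study_data` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_study_csv <- function(study, path) {
  utils::write.csv(as.data.frame(study)[, c("subject_id", "item_id",
                                            "response_a", "response_b")],
                   path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
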