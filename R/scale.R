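#' Ordered response scale
#'
#' An ordered categorical rating scale with `m` verbal categories coded
#' internally as the integers `1..m`.  All measures in this package are
#' rank-invariant, so only the category order carries information; the
#' label-to-code mapping lives exclusively in this object.
#'
#' @param labels Character vector of distinct category names, in
#'   increasing order of the construct (e.g. increasing problem level).
#' @return An object of class `response_scale` with elements `labels`,
#'   `codes` (integers `1..m`) and `m`.
#' @examples
#' sc <- response_scale(c("low", "mid", "high"))
#' sc$m
#' @seealso [icf_qualifier_scale()] for the default five-point scale.
#' @export
response_scale <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 2L)
    stop("a response scale needs at least 2 categories")
  if (anyDuplicated(labels))
    stop("scale labels must be distinct")
  if (anyNA(labels) || any(!nzchar(labels)))
    stop("scale labels must be non-missing and non-empty")
  structure(
    list(labels = labels,
         codes  = seq_along(labels),
         m      = length(labels)),
    class = "response_scale")
}

#' The five-point problem scale (ICF qualifier)
#'
#' The default scale of this package: the five ordered problem levels
#' used when rating each item of an ICF-based questionnaire, from no
#' problems (code 1) to total problems (code 5).
#'
#' @return A `response_scale` with `m = 5` and labels
#'   `no`, `slight`, `moderate`, `major`, `total`.
#' @export
icf_qualifier_scale <- function() {
  response_scale(c("no", "slight", "moderate", "major", "total"))
}

#' @export
print.response_scale <- function(x, ...) {
  cat("Ordered response scale with", x$m, "categories:\n")
  cat(" ", paste(sprintf("%d=%s", x$codes, x$labels), collapse = " < "), "\n")
  invisible(x)
}

# map raw responses (integer codes as strings, or exact labels) to codes;
# NA/blank stays NA, anything else is NA_integer_ with attr "bad" row index
decode_responses <- function(x, scale) {
  x <- as.character(x)
  out <- rep(NA_integer_, length(x))
  blank <- is.na(x) | !nzchar(trimws(x))
  x[!blank] <- trimws(x[!blank])
  numish <- !blank & grepl("^[0-9]+$", x)
  out[numish] <- as.integer(x[numish])
  lab <- !blank & !numish
  out[lab] <- match(x[lab], scale$labels)
  bad <- which(!blank & (is.na(out) | out < 1L | out > scale$m))
  attr(out, "bad") <- bad
  out
}
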