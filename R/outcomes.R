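#' Dichotomize clinical outcomes
#'
#' Maps the 90-day modified Rankin Scale and admission NIHSS onto the three
#' binary endpoints used throughout the evaluation: mortality (mRS90 = 6),
#' disability (mRS90 >= 2, i.e. "mRS90 0-1" versus "2-6") and severity
#' (NIHSS >= 15). Vectorized; `NA` propagates so that complete-case
#' exclusion can be applied downstream.
#'
#' @param mrs90 Integer vector, 0-6.
#' @param nihss Integer vector, 0-42, same length.
#' @return Tibble with 0/1 columns `mortality`, `disability`, `severity`.
#' @export
#' @examples
#' dichotomize_outcomes(c(6, 1, 2), c(20, 14, 15))
dichotomize_outcomes <- function(mrs90, nihss) {
  stopifnot(length(mrs90) == length(nihss))
  if (any(!is.na(mrs90) & (mrs90 < 0 | mrs90 > 6 | mrs90 != round(mrs90)))) {
    stop("mrs90 must be integers in 0..6", call. = FALSE)
  }
  if (any(!is.na(nihss) & (nihss < 0 | nihss > 42 | nihss != round(nihss)))) {
    stop("nihss must be integers in 0..42", call. = FALSE)
  }
  tibble::tibble(
    mortality = as.integer(mrs90 == 6),
    disability = as.integer(mrs90 >= 2),
    severity = as.integer(nihss >= 15)
  )
}

#' Binary outcome labels for ROC analysis
#'
#' Light container pairing a 0/1 label vector with the clinical meaning of
#' the positive class. ROC computations require at least one case and one
#' control.
#'
#' @param labels Vector of 0/1 (or logical).
#' @param positive_meaning One of `"mortality"`, `"disability"`,
#'   `"severity"`, or another short label.
#' @return An `outcome_labels` object with `labels`, `positive_meaning`,
#'   `n_pos`, `n_neg`.
#' @export
outcome_labels <- function(labels, positive_meaning = "outcome") {
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be 0/1 with no missing values", call. = FALSE)
  }
  structure(
    list(
      labels = labels,
      positive_meaning = positive_meaning,
      n_pos = sum(labels == 1L),
      n_neg = sum(labels == 0L)
    ),
    class = "outcome_labels"
  )
}

as_outcome_labels <- function(labels, positive_meaning = "outcome") {
  if (inherits(labels, "outcome_labels")) labels else {
    outcome_labels(labels, positive_meaning)
  }
}
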