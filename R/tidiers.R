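#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn roc_curve `tidy()` returns the operating points, one row per
#'   criterion.
#' @param x A `roc_result`.
#' @param ... Unused.
#' @export
tidy.roc_result <- function(x, ...) {
  x$operating_points
}

#' @describeIn roc_curve `glance()` returns a one-row AUC summary.
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(
    outcome = x$positive_meaning,
    auc = x$auc, auc_se = x$auc_se,
    ci_low = x$ci95[1], ci_high = x$ci95[2],
    n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' @describeIn icc `glance()` returns a one-row summary of the reliability
#'   estimate.
#' @param x An `icc_result`.
#' @param ... Unused.
#' @export
glance.icc_result <- function(x, ...) {
  tibble::tibble(
    icc = x$icc, ci_low = x$ci95[1], ci_high = x$ci95[2],
    band = x$band, n_subjects = x$n, k_raters = x$k
  )
}

#' @describeIn compute_score `tidy()` returns the triggered items, one row
#'   per deduction.
#' @param x A `score_result`.
#' @param ... Unused.
#' @export
tidy.score_result <- function(x, ...) {
  dplyr::mutate(
    x$triggered,
    patient_id = x$patient_id, scheme = x$scheme,
    .before = 1
  )
}

#' @describeIn compute_score `glance()` returns a one-row score summary.
#' @export
glance.score_result <- function(x, ...) {
  tibble::tibble(
    patient_id = x$patient_id, scheme = x$scheme,
    score = x$score, max_score = x$max_score,
    n_triggered = nrow(x$triggered)
  )
}
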