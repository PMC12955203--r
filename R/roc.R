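#' Empirical ROC curve for a clot burden score
#'
#' Builds the empirical ROC of an integer prognostic score against a binary
#' outcome under the orientation used for clot burden scores: a *low* score
#' predicts the adverse outcome, so the positivity rule at criterion `c` is
#' `score <= c`. Operating points are enumerated over every distinct
#' observed score value.
#'
#' The AUC is the Mann-Whitney statistic
#' \eqn{P(S_{pos} < S_{neg}) + \tfrac{1}{2} P(S_{pos} = S_{neg})}, which
#' equals the trapezoidal area under the empirical operating points. Its
#' standard error comes from DeLong's structural-components estimator: with
#' per-case components \eqn{V^{10}_i} (each case against all controls) and
#' per-control components \eqn{V^{01}_j},
#' \eqn{\widehat{var} = s^2_{10}/m + s^2_{01}/n}. The 95% CI is the normal
#' interval truncated to [0, 1].
#'
#' @param scores Numeric (typically integer 0-10) score vector.
#' @param labels 0/1 vector or [outcome_labels()]; both classes must be
#'   present.
#' @param positive_meaning Label for the adverse outcome (used in printing
#'   and plots).
#' @return A `roc_result`: `operating_points` tibble (criterion,
#'   sensitivity, specificity), `auc`, `auc_se`, `ci95`, `n_pos`, `n_neg`,
#'   `positive_meaning`.
#' @export
#' @examples
#' r <- roc_curve(c(0, 1, 8, 9), c(1, 1, 0, 0))
#' r$auc # 1: cases score low, controls high
roc_curve <- function(scores, labels, positive_meaning = NULL) {
  labels <- as_outcome_labels(labels)
  if (!is.null(positive_meaning)) labels$positive_meaning <- positive_meaning
  scores <- as.numeric(scores)
  stopifnot(length(scores) == length(labels$labels))
  if (anyNA(scores)) stop("scores contain missing values", call. = FALSE)
  if (labels$n_pos < 1L || labels$n_neg < 1L) {
    stop("degenerate labels: need at least one case and one control",
      call. = FALSE
    )
  }
  pos <- scores[labels$labels == 1L]
  neg <- scores[labels$labels == 0L]

  crit <- sort(unique(scores))
  op <- tibble::tibble(
    criterion = crit,
    sensitivity = vapply(crit, function(c) mean(pos <= c), numeric(1)),
    specificity = vapply(crit, function(c) mean(neg > c), numeric(1))
  )

  comp <- delong_components(scores, labels$labels)
  auc <- comp$auc
  v <- comp$var
  se <- sqrt(v)
  ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)

  structure(
    list(
      operating_points = op,
      auc = auc, auc_se = se, ci95 = ci,
      n_pos = labels$n_pos, n_neg = labels$n_neg,
      positive_meaning = labels$positive_meaning
    ),
    class = "roc_result"
  )
}

# Mann-Whitney AUC and DeLong structural components under the "low score is
# positive" orientation. Midrank formulation: V10_i compares case i with all
# controls, V01_j compares control j with all cases.
delong_components <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  m <- length(pos)
  n <- length(neg)
  v10 <- vapply(
    pos,
    function(x) mean((x < neg) + 0.5 * (x == neg)), numeric(1)
  )
  v01 <- vapply(
    neg,
    function(y) mean((pos < y) + 0.5 * (pos == y)), numeric(1)
  )
  auc <- mean(v10)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  list(auc = auc, v10 = v10, v01 = v01, var = s10 / m + s01 / n)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(
    sprintf(
      "<roc_result> %s: AUC %.4f (SE %.4f, 95%% CI %.4f-%.4f), %d cases / %d controls\n",
      x$positive_meaning, x$auc, x$auc_se, x$ci95[1], x$ci95[2],
      x$n_pos, x$n_neg
    )
  )
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the *same* patients against
#' the same binary outcome. The variance of the AUC difference uses the
#' paired DeLong covariance of the structural components:
#' \eqn{var(\Delta) = var(V^{10}_a - V^{10}_b)/m + var(V^{01}_a -
#' V^{01}_b)/n}, and \eqn{z = \Delta / \sqrt{var(\Delta)}} with a two-sided
#' normal p-value.
#'
#' Identical score vectors return `z = 0, p = 1` directly. Zero estimated
#' variance with non-identical scores is reported as an error rather than a
#' silent division by zero.
#'
#' @param scores_a,scores_b Score vectors aligned to the same patients.
#' @param labels 0/1 vector or [outcome_labels()].
#' @return One-row tibble: `auc_a`, `auc_b`, `delta`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as_outcome_labels(labels)
  stopifnot(
    length(scores_a) == length(labels$labels),
    length(scores_b) == length(labels$labels)
  )
  if (labels$n_pos < 1L || labels$n_neg < 1L) {
    stop("degenerate labels: need at least one case and one control",
      call. = FALSE
    )
  }
  ca <- delong_components(as.numeric(scores_a), labels$labels)
  cb <- delong_components(as.numeric(scores_b), labels$labels)
  delta <- ca$auc - cb$auc
  if (isTRUE(all.equal(as.numeric(scores_a), as.numeric(scores_b)))) {
    return(tibble::tibble(
      auc_a = ca$auc, auc_b = cb$auc, delta = 0, z = 0, p_value = 1
    ))
  }
  m <- labels$n_pos
  n <- labels$n_neg
  v10d <- ca$v10 - cb$v10
  v01d <- ca$v01 - cb$v01
  var_delta <- (if (m > 1) stats::var(v10d) else 0) / m +
    (if (n > 1) stats::var(v01d) else 0) / n
  if (var_delta <= 0) {
    stop("zero estimated variance for the AUC difference with non-identical scores",
      call. = FALSE
    )
  }
  z <- delta / sqrt(var_delta)
  tibble::tibble(
    auc_a = ca$auc, auc_b = cb$auc, delta = delta,
    z = z, p_value = 2 * stats::pnorm(-abs(z))
  )
}

#' Youden index criterion selection
#'
#' Maximizes J = sensitivity + specificity - 1 over the ROC operating
#' points. Ties are broken toward the smallest criterion (the more specific
#' operating point, matching the convention of reporting the "<= c" rule
#' with highest specificity).
#'
#' @param roc A `roc_result` from [roc_curve()].
#' @return One-row tibble: `j`, `criterion`, `sensitivity`, `specificity`.
#' @export
youden_index <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  op <- roc$operating_points
  j <- op$sensitivity + op$specificity - 1
  best <- which(j == max(j))[1L] # points ordered by criterion, so first = smallest
  tibble::tibble(
    j = j[best],
    criterion = op$criterion[best],
    sensitivity = op$sensitivity[best],
    specificity = op$specificity[best]
  )
}

#' Post-hoc power for a paired AUC difference
#'
#' Normal-approximation power for a two-sided test of the difference between
#' two correlated AUCs, with each AUC's variance from the Hanley-McNeil
#' formula and a user-supplied correlation between the two AUC estimates.
#' Exploratory by design: the correlation between paired AUCs is rarely
#' reported, so the result should be read as a sensitivity analysis over
#' `corr`, not a reconstruction of any published power value.
#'
#' @param auc_a,auc_b AUCs in [0.5, 1).
#' @param n_pos,n_neg Case and control counts.
#' @param alpha Two-sided significance level (default 0.05).
#' @param corr Assumed correlation between the two AUC estimates, in
#'   [0, 1) (default 0.5).
#' @return Power as a single number in [0, 1].
#' @export
auc_power_posthoc <- function(auc_a, auc_b, n_pos, n_neg,
                              alpha = 0.05, corr = 0.5) {
  if (auc_a < 0.5 || auc_a >= 1 || auc_b < 0.5 || auc_b >= 1) {
    stop("AUC values must lie in [0.5, 1)", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (corr < 0 || corr >= 1) stop("corr must be in [0, 1)", call. = FALSE)
  if (n_pos < 1 || n_neg < 1) stop("need positive group sizes", call. = FALSE)

  v1 <- hanley_mcneil_var(auc_a, n_pos, n_neg)
  v2 <- hanley_mcneil_var(auc_b, n_pos, n_neg)
  sd_delta <- sqrt(max(v1 + v2 - 2 * corr * sqrt(v1 * v2), .Machine$double.eps))
  delta <- abs(auc_a - auc_b)
  zcrit <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(delta / sd_delta - zcrit) +
    stats::pnorm(-delta / sd_delta - zcrit)
}

hanley_mcneil_var <- function(a, m, n) {
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  (a * (1 - a) + (m - 1) * (q1 - a^2) + (n - 1) * (q2 - a^2)) / (m * n)
}
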