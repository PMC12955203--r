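#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test on midranks. When the pooled sample is small
#' (n_x + n_y <= 12) and free of ties, the null distribution of the
#' Mann-Whitney statistic is enumerated exactly over all group assignments;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return One-row tibble: `statistic` (Mann-Whitney U for the first
#'   group), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- as.numeric(x[!is.na(x)])
  y <- as.numeric(y[!is.na(y)])
  nx <- length(x)
  ny <- length(y)
  if (nx < 1 || ny < 1) stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(nx)]) # rank sum of x
  u <- w - nx * (nx + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0L

  if (nx + ny <= 12 && !has_ties) {
    # exact: rank-sum distribution over all C(N, nx) assignments
    combos <- utils::combn(nx + ny, nx)
    sums <- colSums(matrix(sort(r)[combos], nrow = nx))
    p <- min(1, 2 * min(mean(sums <= w), mean(sums >= w)))
    method <- "exact enumeration"
  } else {
    mu <- nx * ny / 2
    nties <- table(pooled)
    n <- nx + ny
    sigma2 <- (nx * ny / 12) *
      ((n + 1) - sum(nties^3 - nties) / (n * (n - 1)))
    z <- u - mu
    z <- (z - sign(z) * 0.5) / sqrt(max(sigma2, .Machine$double.eps))
    p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
    method <- "normal approximation with tie and continuity correction"
  }
  tibble::tibble(statistic = u, p_value = p, method = method)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing, over all tables with the observed margins,
#' the hypergeometric probabilities no larger than that of the observed
#' table (with a small relative tolerance for floating-point equality, as
#' is conventional). The odds ratio reported is the sample cross-ratio
#' `a*d / (b*c)`, with `Inf`/`0` conventions for zero cells.
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return One-row tibble: `odds_ratio`, `p_value`.
#' @export
#' @examples
#' fisher_exact(matrix(c(5, 5, 5, 5), 2)) # p = 1
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all margins must be positive", call. = FALSE)
  }
  a <- tab[1, 1]
  m <- sum(tab[1, ]) # first row margin
  n <- sum(tab[2, ])
  kk <- sum(tab[, 1]) # first column margin
  support <- max(0, kk - n):min(kk, m)
  d <- stats::dhyper(support, m, n, kk)
  d_obs <- stats::dhyper(a, m, n, kk)
  p <- min(1, sum(d[d <= d_obs * (1 + 1e-7)]))

  num <- tab[1, 1] * tab[2, 2]
  den <- tab[1, 2] * tab[2, 1]
  or <- if (den == 0 && num == 0) {
    NaN
  } else if (den == 0) {
    Inf
  } else {
    num / den
  }
  tibble::tibble(odds_ratio = or, p_value = p)
}

#' Score-by-outcome contingency counts
#'
#' Tallies patients by observed score value and binary outcome, the layout
#' used to tabulate score levels against good (label 0) versus poor
#' (label 1) 90-day outcomes. Only observed score levels appear; marginal
#' sums reproduce the case/control totals.
#'
#' @param scores Integer score vector.
#' @param labels 0/1 vector or [outcome_labels()].
#' @return Tibble with one row per observed score: `score`, `n_neg`,
#'   `n_pos`.
#' @export
score_outcome_table <- function(scores, labels) {
  labels <- as_outcome_labels(labels)
  stopifnot(length(scores) == length(labels$labels))
  tibble::tibble(score = scores, label = labels$labels) |>
    dplyr::group_by(.data$score) |>
    dplyr::summarise(
      n_neg = sum(.data$label == 0L),
      n_pos = sum(.data$label == 1L),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$score)
}
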