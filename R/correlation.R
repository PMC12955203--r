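#' Spearman rank correlation with tie-corrected midranks
#'
#' Computes rho as the Pearson correlation of midranks (the tie-corrected
#' form) and a two-sided p-value. For n >= 10 the p-value uses the
#' t-approximation with n - 2 degrees of freedom; for smaller samples the
#' permutation null is enumerated exactly over all n! orderings (n <= 8), or
#' sampled by seeded Monte Carlo at n = 9 where full enumeration is
#' impractical.
#'
#' Missing pairs are removed first (complete-case analysis); a constant
#' vector leaves the correlation undefined and raises an error.
#'
#' @param x,y Numeric vectors of equal length, n >= 3 complete pairs.
#' @return A tibble: `rho`, `p_value`, `n`, `method`.
#' @export
#' @examples
#' spearman_test(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10)) # rho = 1
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- as.numeric(x[keep])
  y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)

  if (n >= 10) {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  } else {
    p <- spearman_perm_p(rx, ry)
    method <- "permutation"
  }
  tibble::tibble(
    rho = rho, p_value = min(p, 1), n = n, method = method
  )
}

# Two-sided permutation p for rho on midranks: exact enumeration of all n!
# orderings up to n = 8, seeded Monte Carlo at n = 9.
spearman_perm_p <- function(rx, ry) {
  n <- length(rx)
  cx <- rx - mean(rx)
  cy <- ry - mean(ry)
  denom <- sqrt(sum(cx^2) * sum(cy^2))
  obs <- abs(sum(cx * cy) / denom)
  tol <- 1e-12
  if (n <= 8) {
    # rows of perms index cy; correlate each permuted cy against fixed cx
    perms <- all_permutations(n)
    stat <- abs(apply(perms, 1L, function(idx) sum(cx * cy[idx]))) / denom
    mean(stat >= obs - tol)
  } else {
    with_preserved_seed({
      set.seed(199033L)
      b <- 20000L
      stat <- vapply(
        seq_len(b),
        function(i) abs(sum(cx * cy[sample.int(n)])) / denom,
        numeric(1)
      )
      (1 + sum(stat >= obs - tol)) / (b + 1)
    })
  }
}

# Matrix of all permutations of 1..n, one per row.
all_permutations <- function(n) {
  if (n == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

# Run code without disturbing the caller's RNG stream.
with_preserved_seed <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

#' Spearman correlation within treatment strata
#'
#' Applies [spearman_test()] between a score column and an outcome column
#' separately within each level of a grouping column (e.g. treatment
#' modality). Strata with fewer than 3 complete cases are reported as
#' skipped rather than raising an error, so one thin stratum does not abort
#' a cohort analysis.
#'
#' @param cohort Data frame.
#' @param score_col,outcome_col,group_col Column names (strings).
#' @return Tibble with one row per stratum: `group`, `n`, `rho`, `p_value`,
#'   `method`, `skipped` (reason or `NA`).
#' @export
stratified_spearman <- function(cohort, score_col, outcome_col, group_col) {
  cohort <- tibble::as_tibble(cohort)
  for (col in c(score_col, outcome_col, group_col)) {
    if (!col %in% names(cohort)) {
      stop("unknown column: ", col, call. = FALSE)
    }
  }
  groups <- split(cohort, cohort[[group_col]], drop = TRUE)
  purrr::map_dfr(names(groups), function(g) {
    d <- groups[[g]]
    keep <- stats::complete.cases(d[[score_col]], d[[outcome_col]])
    n <- sum(keep)
    if (n < 3) {
      return(tibble::tibble(
        group = g, n = n, rho = NA_real_, p_value = NA_real_,
        method = NA_character_,
        skipped = "fewer than 3 complete cases"
      ))
    }
    res <- tryCatch(
      spearman_test(d[[score_col]][keep], d[[outcome_col]][keep]),
      error = function(e) NULL
    )
    if (is.null(res)) {
      return(tibble::tibble(
        group = g, n = n, rho = NA_real_, p_value = NA_real_,
        method = NA_character_, skipped = "correlation undefined"
      ))
    }
    tibble::tibble(
      group = g, n = res$n, rho = res$rho, p_value = res$p_value,
      method = res$method, skipped = NA_character_
    )
  })
}
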