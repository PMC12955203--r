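#' Inter-rater reliability: ICC(2,1)
#'
#' Intraclass correlation for absolute agreement between single raters under
#' the two-way random-effects model: both subjects and raters are treated as
#' random samples, so systematic rater offsets count against agreement. From
#' the two-way mean squares (rows MSR, columns MSC, residual MSE),
#' \deqn{ICC(2,1) = \frac{MSR - MSE}{MSR + (k-1)MSE + \frac{k}{n}(MSC - MSE)}}
#' with the 95% confidence interval from the McGraw-Wong F-distribution
#' construction.
#'
#' The qualitative band follows the five-level interpretation scale:
#' poor (< 0.20), fair (0.21-0.40), moderate (0.41-0.60), good (0.61-0.80),
#' very good (0.81-1.0).
#'
#' @param ratings Numeric matrix or data frame, subjects in rows (n >= 5),
#'   raters in columns (k >= 2), no missing cells.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An `icc_result`: `icc`, `ci95`, `band`, `n`, `k`, and the mean
#'   squares used.
#' @export
#' @examples
#' m <- cbind(r1 = c(9, 6, 8, 7, 10, 6), r2 = c(8, 5, 8, 6, 9, 7))
#' icc(m)
icc <- function(ratings, conf_level = 0.95) {
  m <- as.matrix(ratings)
  mode(m) <- "numeric"
  if (anyNA(m)) {
    stop("ratings contain missing cells; complete cases are required",
      call. = FALSE
    )
  }
  n <- nrow(m)
  k <- ncol(m)
  if (n < 5) stop("need at least 5 subjects", call. = FALSE)
  if (k < 2) stop("need at least 2 raters", call. = FALSE)

  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  if (ssr <= .Machine$double.eps * sst) {
    stop("degenerate ratings: zero between-subject variance", call. = FALSE)
  }

  r <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - conf_level
  if (mse <= 0 && msc <= 0) {
    # perfect agreement: no residual or rater variance
    ci <- c(1, 1)
  } else {
    a <- (k * r) / (n * (1 - r))
    b <- 1 + (k * r * (n - 1)) / (n * (1 - r))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    ci <- c(lower, upper)
  }

  structure(
    list(
      icc = r, ci95 = ci, band = icc_band(r), n = n, k = k,
      ms = list(msr = msr, msc = msc, mse = mse),
      conf_level = conf_level
    ),
    class = "icc_result"
  )
}

#' Interpretation band for an ICC value
#'
#' Five-level qualitative scale: poor (< 0.20), fair (0.21-0.40), moderate
#' (0.41-0.60), good (0.61-0.80), very good (0.81-1.0). Values at or below
#' 0.20 (including negative estimates) are "poor".
#'
#' @param x ICC value(s).
#' @return Character vector of bands.
#' @export
#' @examples
#' icc_band(c(0.19, 0.21, 0.41, 0.61, 0.96))
icc_band <- function(x) {
  vapply(x, function(r) {
    if (is.na(r)) {
      NA_character_
    } else if (r <= 0.20) {
      "poor"
    } else if (r <= 0.40) {
      "fair"
    } else if (r <= 0.60) {
      "moderate"
    } else if (r <= 0.80) {
      "good"
    } else {
      "very good"
    }
  }, character(1))
}

#' @export
print.icc_result <- function(x, ...) {
  cat(
    sprintf(
      "<icc_result> ICC(2,1) = %.4f (%d%% CI %.4f-%.4f), %s agreement; n = %d subjects, k = %d raters\n",
      x$icc, round(100 * x$conf_level), x$ci95[1], x$ci95[2], x$band,
      x$n, x$k
    )
  )
  invisible(x)
}
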