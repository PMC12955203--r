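test_that("outcome dichotomization follows the clinical cutoffs", {
  out <- dichotomize_outcomes(c(6, 1, 2, 5), c(20, 14, 15, 10))
  expect_equal(out$mortality, c(1L, 0L, 0L, 0L))
  expect_equal(out$disability, c(1L, 0L, 1L, 1L))
  expect_equal(out$severity, c(1L, 0L, 1L, 0L))
  expect_error(dichotomize_outcomes(7, 10), "mrs90")
  expect_error(dichotomize_outcomes(3, 43), "nihss")
})

test_that("spearman rho equals the Pearson-on-midranks oracle", {
  expect_equal(spearman_test(1:5, c(2, 4, 6, 8, 10))$rho, 1)
  expect_equal(spearman_test(1:5, 5:1)$rho, -1)

  x <- c(1, 2, 2, 4)
  y <- c(3, 1, 4, 4)
  expect_equal(spearman_test(x, y)$rho, oracle_spearman_rho(x, y))

  set.seed(11)
  for (i in 1:10) {
    xr <- sample(0:10, 30, replace = TRUE)
    yr <- sample(0:10, 30, replace = TRUE)
    expect_equal(spearman_test(xr, yr)$rho, oracle_spearman_rho(xr, yr))
  }
  expect_error(spearman_test(rep(3, 5), 1:5), "constant")
})

test_that("spearman p-values: exact permutation below n = 10, t-approximation above", {
  # untied small samples agree with the exact reference distribution
  set.seed(21)
  for (i in 1:5) {
    x <- sample(1:7)
    y <- sample(1:7)
    mine <- spearman_test(x, y)
    expect_equal(mine$method, "permutation")
    ref <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
  # large-sample branch matches the t-approximation reference
  set.seed(22)
  x <- rnorm(40)
  y <- x + rnorm(40, sd = 2)
  mine <- spearman_test(x, y)
  expect_equal(mine$method, "t-approximation")
  ref <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-10)
})

test_that("ROC: AUC is the Mann-Whitney statistic and equals the trapezoid area", {
  expect_equal(roc_curve(c(0, 0, 10, 10), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_curve(rep(4, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  # exhaustive 4-pair enumeration: cases (1,3), controls (2,4)
  r <- roc_curve(c(1, 3, 2, 4), c(1, 1, 0, 0))
  expect_equal(r$auc, oracle_mw_auc(c(1, 3), c(2, 4)))
  expect_equal(r$auc, 0.75)

  set.seed(31)
  for (i in 1:25) {
    fx <- random_roc_fixture(n = 25)
    r <- roc_curve(fx$scores, fx$labels)
    pos <- fx$scores[fx$labels == 1]
    neg <- fx$scores[fx$labels == 0]
    expect_equal(r$auc, oracle_mw_auc(pos, neg), tolerance = 1e-12)
    expect_equal(oracle_trapezoid(r$operating_points), r$auc,
      tolerance = 1e-12
    )
    # operating points: sensitivity grows, specificity shrinks with c
    expect_true(all(diff(r$operating_points$sensitivity) >= 0))
    expect_true(all(diff(r$operating_points$specificity) <= 0))
    expect_true(all(r$ci95 >= 0 & r$ci95 <= 1))
    # orientation invariance: negated scores under the flipped (>= c) rule
    expect_equal(
      mean(outer(-pos, -neg, function(p, n) (p > n) + 0.5 * (p == n))),
      r$auc
    )
  }
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "degenerate")
})

test_that("ROC AUC, DeLong variance and paired test agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(32)
  for (i in 1:5) {
    fx <- random_roc_fixture(n = 40)
    r <- roc_curve(fx$scores, fx$labels)
    pr <- pROC::roc(
      fx$labels, fx$scores,
      direction = ">", levels = c(0, 1), quiet = TRUE
    )
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    expect_equal(r$auc_se^2, as.numeric(pROC::var(pr)), tolerance = 1e-12)

    other <- pmax(pmin(fx$scores + sample(-2:2, 40, TRUE), 10), 0)
    cmp <- delong_test(fx$scores, other, fx$labels)
    pr2 <- pROC::roc(
      fx$labels, other,
      direction = ">", levels = c(0, 1), quiet = TRUE
    )
    ref <- pROC::roc.test(pr, pr2, method = "delong", paired = TRUE)
    expect_equal(abs(cmp$z), abs(unname(ref$statistic)), tolerance = 1e-9)
    expect_equal(cmp$p_value, unname(ref$p.value), tolerance = 1e-9)
  }
})

test_that("paired DeLong test matches the brute-force jackknife oracle", {
  # fixed 10-patient fixture on the printed discrete score scale
  scores_a <- c(1, 2, 0, 5, 3, 7, 8, 6, 9, 4)
  scores_b <- c(2, 1, 3, 4, 6, 8, 7, 9, 10, 5)
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  cmp <- delong_test(scores_a, scores_b, labels)
  jack <- oracle_jackknife(scores_a, scores_b, labels)
  expect_equal(cmp$delta, jack$delta, tolerance = 1e-12)
  expect_equal(cmp$z, jack$z, tolerance = 1e-6)
  expect_equal(cmp$p_value, jack$p, tolerance = 1e-6)

  # self-comparison and symmetry
  self <- delong_test(scores_a, scores_a, labels)
  expect_equal(self$delta, 0)
  expect_equal(self$z, 0)
  expect_equal(self$p_value, 1)
  swapped <- delong_test(scores_b, scores_a, labels)
  expect_equal(swapped$delta, -cmp$delta)
  expect_equal(swapped$z, -cmp$z)
  expect_equal(swapped$p_value, cmp$p_value)
})

test_that("Youden criterion maximizes J with the smallest-criterion tie-break", {
  perfect <- roc_curve(c(0, 0, 10, 10), c(1, 1, 0, 0))
  expect_equal(youden_index(perfect)$j, 1)
  flat <- roc_curve(rep(4, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(youden_index(flat)$j, 0)

  # cases (1,3), controls (2,4): J = 0.5 at both c=1 and c=3; pick c=1
  y <- youden_index(roc_curve(c(1, 3, 2, 4), c(1, 1, 0, 0)))
  expect_equal(y$j, 0.5)
  expect_equal(y$criterion, 1)
  expect_equal(y$sensitivity, 0.5)
  expect_equal(y$specificity, 1)

  # reported point always recomputes J exactly
  set.seed(41)
  for (i in 1:10) {
    fx <- random_roc_fixture()
    y <- youden_index(roc_curve(fx$scores, fx$labels))
    expect_equal(y$j, y$sensitivity + y$specificity - 1)
  }
})

test_that("ICC(2,1) matches the aov mean-squares oracle and handles edge cases", {
  m <- cbind(r1 = c(9, 6, 8, 7, 10, 6), r2 = c(8, 5, 8, 6, 9, 7))
  res <- icc(m)
  # independent two-way decomposition via stats::aov
  d <- data.frame(
    y = as.vector(m),
    subject = factor(rep(seq_len(nrow(m)), ncol(m))),
    rater = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  ms <- summary(stats::aov(y ~ subject + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]
  msc <- ms[2]
  mse <- ms[3]
  n <- nrow(m)
  k <- ncol(m)
  oracle <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  expect_equal(res$icc, unname(oracle), tolerance = 1e-9)
  expect_true(res$ci95[1] <= res$icc && res$icc <= res$ci95[2])

  identical_raters <- cbind(a = c(1, 4, 2, 8, 5), b = c(1, 4, 2, 8, 5))
  perfect <- icc(identical_raters)
  expect_equal(perfect$icc, 1)
  expect_equal(perfect$band, "very good")

  m_na <- m
  m_na[2, 1] <- NA
  expect_error(icc(m_na), "missing cells")
  expect_error(icc(matrix(5, 6, 2)), "between-subject")
  expect_error(icc(m[1:4, ]), "at least 5")
})

test_that("ICC interpretation bands reproduce the five-level table", {
  expect_equal(
    icc_band(c(0.05, 0.19, 0.21, 0.40, 0.41, 0.60, 0.61, 0.80, 0.81, 0.96, 1.0)),
    c(
      "poor", "poor", "fair", "fair", "moderate", "moderate",
      "good", "good", "very good", "very good", "very good"
    )
  )
  expect_equal(icc_band(-0.3), "poor")
})

test_that("ICC is centred on zero for independent raters", {
  set.seed(51)
  vals <- replicate(100, icc(cbind(rnorm(500), rnorm(500)))$icc)
  expect_gt(mean(vals), -0.1)
  expect_lt(mean(vals), 0.1)
})

test_that("wilcoxon rank-sum: exact enumeration and tie-corrected approximation", {
  same <- wilcoxon_rank_sum(c(1, 2, 2, 5), c(1, 2, 2, 5))
  expect_gte(same$p_value, 0.99)

  sep <- wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$method, "exact enumeration")
  expect_equal(sep$p_value, oracle_wilcoxon_exact_p(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(sep$p_value, 0.1)

  # symmetry and agreement with the standard reference in both branches
  set.seed(61)
  for (i in 1:5) {
    x <- sample(1:50, 5)
    y <- sample(51:100, 6)
    x <- x + runif(5) # ensure untied
    y <- y + runif(6)
    mine <- wilcoxon_rank_sum(x, y)
    expect_equal(mine$p_value, wilcoxon_rank_sum(y, x)$p_value)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
  for (i in 1:5) {
    x <- sample(0:10, 20, replace = TRUE)
    y <- sample(2:12, 25, replace = TRUE)
    mine <- wilcoxon_rank_sum(x, y)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    )
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-10)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("fisher exact test sums the hypergeometric tail correctly", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1)

  tab <- matrix(c(3, 1, 1, 3), 2)
  mine <- fisher_exact(tab)
  expect_equal(mine$p_value, oracle_fisher_p(tab))
  expect_equal(mine$p_value, 34 / 70, tolerance = 1e-12)
  expect_equal(mine$odds_ratio, 9)

  set.seed(71)
  for (i in 1:10) {
    t2 <- matrix(rpois(4, 6) + 1, 2)
    mine <- fisher_exact(t2)
    expect_equal(mine$p_value, fisher_exact(t(t2))$p_value)
    ref <- stats::fisher.test(t2)
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-10)
    expect_gt(mine$p_value, 0)
    expect_lte(mine$p_value, 1)
    # hypergeometric pmf over all tables with these margins is a distribution
    m <- sum(t2[1, ])
    n <- sum(t2[2, ])
    k <- sum(t2[, 1])
    support <- max(0, k - n):min(k, m)
    expect_equal(sum(stats::dhyper(support, m, n, k)), 1, tolerance = 1e-12)
  }
  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2)), "margins")
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("score-outcome contingency table conserves counts", {
  tab <- score_outcome_table(c(0, 0, 5, 5), c(1, 1, 0, 0))
  expect_equal(tab$score, c(0, 5))
  expect_equal(tab$n_pos, c(2L, 0L))
  expect_equal(tab$n_neg, c(0L, 2L))

  set.seed(81)
  scores <- sample(0:10, 60, replace = TRUE)
  labels <- rbinom(60, 1, 0.5)
  tab <- score_outcome_table(scores, labels)
  expect_equal(sum(tab$n_pos) + sum(tab$n_neg), 60L)
  expect_equal(sum(tab$n_pos), sum(labels))
  expect_setequal(tab$score, unique(scores)) # no empty levels
})

test_that("stratified spearman mirrors pooled analysis and skips thin strata", {
  set.seed(91)
  d <- tibble::tibble(
    score = sample(0:10, 40, replace = TRUE),
    outcome = sample(0:6, 40, replace = TRUE),
    grp = "all"
  )
  strat <- stratified_spearman(d, "score", "outcome", "grp")
  pooled <- spearman_test(d$score, d$outcome)
  expect_equal(nrow(strat), 1L)
  expect_equal(strat$rho, pooled$rho)
  expect_equal(strat$p_value, pooled$p_value)

  d2 <- dplyr::bind_rows(
    dplyr::mutate(d, grp = "A"),
    dplyr::mutate(d, grp = "B"),
    tibble::tibble(score = c(1, 2), outcome = c(3, 4), grp = "C")
  )
  strat2 <- stratified_spearman(d2, "score", "outcome", "grp")
  expect_equal(
    strat2$rho[strat2$group == "A"], strat2$rho[strat2$group == "B"]
  )
  expect_match(strat2$skipped[strat2$group == "C"], "fewer than 3")
  expect_error(stratified_spearman(d, "score", "outcome", "nope"), "unknown column")
})

test_that("post-hoc AUC power behaves like a two-sided test", {
  expect_equal(
    auc_power_posthoc(0.75, 0.75, 50, 80, alpha = 0.05, corr = 0.5), 0.05,
    tolerance = 1e-12
  )
  # monotone in the AUC gap
  gaps <- seq(0, 0.15, by = 0.03)
  pw <- vapply(
    gaps,
    function(g) auc_power_posthoc(0.7 + g, 0.7, 83, 47, corr = 0.5),
    numeric(1)
  )
  expect_true(all(diff(pw) > 0))

  # numeric-integration oracle for a fixed tuple: integrate the normal
  # density of the test statistic over the rejection region
  v1 <- clotburden:::hanley_mcneil_var(0.807, 83, 47)
  v2 <- clotburden:::hanley_mcneil_var(0.735, 83, 47)
  sd_delta <- sqrt(v1 + v2 - 2 * 0.5 * sqrt(v1 * v2))
  mu <- (0.807 - 0.735) / sd_delta
  zc <- qnorm(0.975)
  oracle <- stats::integrate(
    function(z) dnorm(z, mean = mu), zc, Inf
  )$value +
    stats::integrate(function(z) dnorm(z, mean = mu), -Inf, -zc)$value
  expect_equal(
    auc_power_posthoc(0.807, 0.735, 83, 47, corr = 0.5), oracle,
    tolerance = 1e-6
  )
  expect_error(auc_power_posthoc(0.4, 0.7, 10, 10), "AUC")
  expect_error(auc_power_posthoc(0.7, 0.7, 10, 10, alpha = 0), "alpha")
  expect_error(auc_power_posthoc(0.7, 0.7, 10, 10, corr = 1), "corr")
})
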