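# Independent brute-force oracles used to pin down expected values.
# Deliberately written with elementary arithmetic, not via the package's own
# code paths.

# Midrank of each element: count of smaller values + half the tied block.
oracle_midrank <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
}

oracle_pearson <- function(a, b) {
  ca <- a - mean(a)
  cb <- b - mean(b)
  sum(ca * cb) / sqrt(sum(ca^2) * sum(cb^2))
}

oracle_spearman_rho <- function(x, y) {
  oracle_pearson(oracle_midrank(x), oracle_midrank(y))
}

# Mann-Whitney AUC by exhaustive case-control pair enumeration, with the
# low-score-positive orientation: a case scoring below a control counts 1.
oracle_mw_auc <- function(pos, neg) {
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + (p < n) + 0.5 * (p == n)
    }
  }
  total / (length(pos) * length(neg))
}

# Trapezoidal area under the (FPR, TPR) polygon through the operating points.
oracle_trapezoid <- function(op) {
  fpr <- c(1, 1 - op$specificity, 0) # criterion descending -> fpr descending
  tpr <- c(1, op$sensitivity, 0)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]
  tpr <- tpr[ord]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Grouped delete-one jackknife for one AUC and for a paired AUC difference,
# recomputing every leave-one-out AUC by brute force.
oracle_jackknife <- function(scores_a, scores_b, labels) {
  pa <- scores_a[labels == 1]
  na <- scores_a[labels == 0]
  pb <- scores_b[labels == 1]
  nb <- scores_b[labels == 0]
  m <- length(pa)
  n <- length(na)
  jack_var <- function(theta) {
    k <- length(theta)
    (k - 1) / k * sum((theta - mean(theta))^2)
  }
  a_pos <- vapply(seq_len(m), function(i) oracle_mw_auc(pa[-i], na), numeric(1))
  a_neg <- vapply(seq_len(n), function(j) oracle_mw_auc(pa, na[-j]), numeric(1))
  b_pos <- vapply(seq_len(m), function(i) oracle_mw_auc(pb[-i], nb), numeric(1))
  b_neg <- vapply(seq_len(n), function(j) oracle_mw_auc(pb, nb[-j]), numeric(1))
  var_a <- jack_var(a_pos) + jack_var(a_neg)
  var_delta <- jack_var(a_pos - b_pos) + jack_var(a_neg - b_neg)
  delta <- oracle_mw_auc(pa, na) - oracle_mw_auc(pb, nb)
  z <- delta / sqrt(var_delta)
  list(
    var_a = var_a, var_delta = var_delta, delta = delta,
    z = z, p = 2 * stats::pnorm(-abs(z))
  )
}

# Exact two-sided rank-sum p by enumerating group assignments of the pooled
# observations themselves.
oracle_wilcoxon_exact_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  r <- oracle_midrank(pooled)
  obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(length(pooled), nx)
  sums <- apply(combos, 2, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(sums <= obs), mean(sums >= obs)))
}

# Fisher two-sided p by direct hypergeometric enumeration using choose().
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  prob <- vapply(
    support,
    function(a) choose(m, a) * choose(n, k - a) / choose(m + n, k),
    numeric(1)
  )
  obs <- choose(m, tab[1, 1]) * choose(n, k - tab[1, 1]) / choose(m + n, k)
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# Item-by-item deduction sum for a status, coded independently of the
# scoring_scheme machinery (fixed tables for both built-in schemes).
oracle_builtin_score <- function(status, scheme_name) {
  d <- 0
  if (scheme_name == "cbs") {
    d <- d + 2 * status[["ica_supraclinoid"]] + 1 * status[["ica_infraclinoid"]]
  } else {
    d <- d + 3 * (status[["ica_supraclinoid"]] || status[["ica_infraclinoid"]])
  }
  d <- d + 2 * status[["m1_proximal"]] + 2 * status[["m1_distal"]] +
    1 * status[["aca"]] + 1 * status[["m2_superior"]] +
    1 * status[["m2_inferior"]]
  10 - d
}

# All 2^7 segment statuses as a logical matrix.
all_statuses <- function() {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 7))
  names(grid) <- segment_names()
  as.matrix(grid)
}

# Small random score/label fixture with both classes guaranteed.
random_roc_fixture <- function(n = 30, score_max = 10) {
  repeat {
    scores <- sample(0:score_max, n, replace = TRUE)
    labels <- stats::rbinom(n, 1, 0.4)
    if (sum(labels) >= 3 && sum(1 - labels) >= 3) {
      return(list(scores = scores, labels = labels))
    }
  }
}
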