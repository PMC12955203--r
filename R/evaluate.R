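round4 <- function(x) round(as.numeric(x), 4) # statistics
pct2 <- function(x) round(100 * as.numeric(x), 2) # percentages, 0-100 scale

#' Run the full score-versus-outcome evaluation
#'
#' Orchestrates the whole comparison battery on one cohort: scores every
#' patient under both built-in schemes, dichotomizes the outcomes
#' (mortality mRS90 = 6, disability mRS90 >= 2, severity NIHSS >= 15), and
#' assembles a deterministic report with
#' \itemize{
#'   \item `correlations`: Spearman rho of each scheme against NIHSS,
#'     ASPECTS and mRS90;
#'   \item `outcome_correlations`: rho against the three binary endpoints;
#'   \item `roc`: per outcome and scheme the AUC, DeLong SE, 95% CI and the
#'     Youden-selected criterion with sensitivity/specificity (percent);
#'   \item `paired_tests`: paired DeLong comparison (modified minus
#'     original) per outcome;
#'   \item `stratified`: per-treatment Spearman correlations when a strata
#'     column is supplied;
#'   \item `contingency`: score-by-outcome counts for the disability
#'     dichotomy;
#'   \item `icc`: inter-rater ICC(2,1) per scheme when rater columns are
#'     present;
#'   \item `power`: exploratory post-hoc power for the disability AUC
#'     difference.
#' }
#' An outcome with only one class present is replaced by a degeneracy
#' notice rather than an error. Statistics are half-even rounded to 4
#' decimals and percentages to 2, so identical cohorts yield byte-identical
#' JSON reports.
#'
#' @param cohort A `cohort_table` (or data frame in the cohort schema).
#' @param strata Optional grouping column name for stratified correlations
#'   (e.g. `"treatment"`); `NULL` disables stratification.
#' @param power_corr Assumed correlation between paired AUC estimates for
#'   the exploratory power section (default 0.5).
#' @return A `cbs_evaluation` nested list; serialize with [write_report()].
#' @export
run_evaluation <- function(cohort, strata = "treatment", power_corr = 0.5) {
  if (!inherits(cohort, "cohort_table")) {
    cohort <- as_cohort_table(cohort)
  }
  quarantine <- attr(cohort, "quarantine")
  scored <- add_scores(cohort)
  outcomes <- dichotomize_outcomes(scored$mrs90, scored$nihss)
  scored <- dplyr::bind_cols(scored, outcomes)
  schemes <- c(cbs = "cbs", mcbs = "mcbs")
  endpoints <- c("mortality", "disability", "severity")

  corr_section <- function(targets) {
    purrr::map(schemes, function(sc) {
      purrr::map(targets, function(tg) {
        res <- tryCatch(
          spearman_test(scored[[sc]], scored[[tg]]),
          error = function(e) NULL
        )
        if (is.null(res)) {
          return(list(degenerate = "correlation undefined (constant vector)"))
        }
        list(
          rho = round4(res$rho), p_value = round4(res$p_value),
          n = res$n, method = res$method
        )
      })
    })
  }

  roc_objects <- purrr::map(endpoints, function(ep) {
    lab <- scored[[ep]]
    if (sum(lab) == 0L || sum(lab) == length(lab)) {
      return(NULL)
    }
    purrr::map(schemes, function(sc) {
      roc_curve(scored[[sc]], lab, positive_meaning = ep)
    })
  })
  names(roc_objects) <- endpoints

  roc_section <- purrr::map(roc_objects, function(pair) {
    if (is.null(pair)) {
      return(list(
        degenerate = "outcome has a single class; ROC analysis not defined"
      ))
    }
    purrr::map(pair, function(r) {
      yj <- youden_index(r)
      list(
        auc = round4(r$auc), auc_se = round4(r$auc_se),
        ci95 = c(round4(r$ci95[1]), round4(r$ci95[2])),
        n_pos = r$n_pos, n_neg = r$n_neg,
        youden = list(
          j = round4(yj$j),
          criterion = paste0("<=", yj$criterion),
          sensitivity_pct = pct2(yj$sensitivity),
          specificity_pct = pct2(yj$specificity)
        )
      )
    })
  })

  paired_section <- purrr::map(roc_objects, function(pair) {
    if (is.null(pair)) {
      return(list(
        degenerate = "outcome has a single class; paired test not defined"
      ))
    }
    ep <- pair$cbs$positive_meaning
    cmp <- delong_test(
      scored$mcbs, scored$cbs, scored[[ep]]
    )
    list(
      auc_mcbs = round4(cmp$auc_a), auc_cbs = round4(cmp$auc_b),
      delta = round4(cmp$delta), z = round4(cmp$z),
      p_value = round4(cmp$p_value)
    )
  })

  stratified_section <- NULL
  if (!is.null(strata) && strata %in% names(scored) &&
    dplyr::n_distinct(scored[[strata]]) > 1L) {
    stratified_section <- purrr::map(schemes, function(sc) {
      purrr::map(
        stats::setNames(endpoints, endpoints),
        function(ep) {
          tab <- stratified_spearman(scored, sc, ep, strata)
          purrr::map(
            stats::setNames(seq_len(nrow(tab)), tab$group),
            function(i) {
              if (!is.na(tab$skipped[i])) {
                list(n = tab$n[i], skipped = tab$skipped[i])
              } else {
                list(
                  rho = round4(tab$rho[i]),
                  p_value = round4(tab$p_value[i]), n = tab$n[i]
                )
              }
            }
          )
        }
      )
    })
  }

  contingency_section <- purrr::map(schemes, function(sc) {
    tab <- score_outcome_table(scored[[sc]], scored$disability)
    purrr::map(seq_len(nrow(tab)), function(i) {
      list(
        score = tab$score[i],
        mrs90_0_1 = tab$n_neg[i],
        mrs90_2_6 = tab$n_pos[i]
      )
    })
  })

  icc_section <- NULL
  rater_sets <- list(
    cbs = c("cbs_rater1", "cbs_rater2"),
    mcbs = c("mcbs_rater1", "mcbs_rater2")
  )
  if (all(unlist(rater_sets) %in% names(scored))) {
    icc_section <- purrr::map(rater_sets, function(cols) {
      res <- icc(as.matrix(scored[cols]))
      list(
        icc = round4(res$icc),
        ci95 = c(round4(res$ci95[1]), round4(res$ci95[2])),
        band = res$band, n = res$n, k = res$k
      )
    })
  }

  power_section <- NULL
  dis <- roc_objects$disability
  if (!is.null(dis)) {
    aucs <- sort(c(dis$cbs$auc, dis$mcbs$auc))
    if (aucs[1] >= 0.5 && aucs[2] < 1) {
      power_section <- list(
        power = round4(auc_power_posthoc(
          aucs[2], aucs[1], dis$cbs$n_pos, dis$cbs$n_neg,
          alpha = 0.05, corr = power_corr
        )),
        alpha = 0.05, corr = power_corr,
        note = paste(
          "exploratory Hanley-McNeil approximation with an assumed",
          "correlation between the paired AUC estimates"
        )
      )
    }
  }

  report <- list(
    meta = list(
      n = nrow(scored),
      n_excluded = nrow(quarantine),
      excluded = if (nrow(quarantine)) {
        purrr::map(seq_len(nrow(quarantine)), function(i) {
          list(
            patient_id = quarantine$patient_id[i],
            reason = quarantine$reason[i]
          )
        })
      } else {
        list()
      },
      provenance = attr(cohort, "provenance") %||% "in-memory",
      outcome_definitions = list(
        mortality = "mrs90 == 6",
        disability = "mrs90 >= 2",
        severity = "nihss >= 15"
      ),
      schemes = purrr::map(schemes, function(sc) {
        s <- builtin_scheme(sc)
        purrr::map(seq_len(nrow(s$items)), function(i) {
          list(
            item = s$items$item[i],
            segments = s$items$segments[[i]],
            deduction = s$items$deduction[i]
          )
        })
      })
    ),
    correlations = corr_section(
      c(nihss = "nihss", aspects = "aspects", mrs90 = "mrs90")
    ),
    outcome_correlations = corr_section(
      stats::setNames(endpoints, endpoints)
    ),
    roc = roc_section,
    paired_tests = paired_section,
    stratified = stratified_section,
    contingency = contingency_section,
    icc = icc_section,
    power = power_section
  )
  report <- report[!vapply(report, is.null, logical(1))]
  structure(report, class = "cbs_evaluation")
}

#' Serialize an evaluation report to JSON
#'
#' Stable key order and fixed rounding (done in [run_evaluation()]) make
#' repeated runs on the same cohort byte-identical.
#'
#' @param report A `cbs_evaluation`.
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "cbs_evaluation"))
  json <- jsonlite::toJSON(
    unclass(report),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null",
    null = "null"
  )
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
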