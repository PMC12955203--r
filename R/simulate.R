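#' Configure the synthetic stroke-cohort generator
#'
#' Parameterizes a generative model for anterior-circulation LVO cohorts:
#' an anatomically structured occlusion process (an occlusion origin that
#' propagates distally along ICA -> proximal M1 -> distal M1 -> M2
#' branches), a latent severity score driven by per-item segment weights,
#' and clinical scales (NIHSS, ASPECTS, mRS at admission and 90 days)
#' generated from that latent severity. Defaults emulate a 130-patient
#' MCA-territory cohort with admission NIHSS around 14.8, roughly 22%
#' 90-day mortality and 64% disability; they were calibrated once against
#' those marginal targets and then frozen.
#'
#' @param seed Integer RNG seed (required; the cohort is reproducible
#'   bit-for-bit from the config).
#' @param n Cohort size, >= 10 (default 130).
#' @param p_origin Probability weights over the occlusion origin
#'   `c(ica, m1, m2, none)`; normalized to sum to 1.
#' @param p_extend_distal Probability that involvement at one level extends
#'   to the next distal level (ICA -> M1 proximal -> M1 distal -> each M2
#'   branch).
#' @param p_supra_only,p_infra_only,p_both_ica Conditional ICA sub-pattern
#'   probabilities given an ICA origin; must sum to 1.
#' @param p_aca Probability of ACA involvement given ICA occlusion.
#' @param w_true Named item weights on latent severity for
#'   `c(ica, m1_proximal, m1_distal, aca, m2_superior, m2_inferior)`; the
#'   `ica` weight applies once when either ICA segment is involved,
#'   mirroring the scheme structure. Default is proportional to the
#'   modified-scheme deductions (ICA-heavy).
#' @param sigma_latent SD of the latent severity noise.
#' @param nihss_map `c(intercept, slope, sd)` mapping latent severity to
#'   admission NIHSS (rounded, clamped to 0-42).
#' @param aspects_map `c(intercept, slope, sd)` for ASPECTS (clamped 0-10);
#'   slope is negative (more burden, less salvageable tissue).
#' @param mrs_thresholds Six strictly increasing cut-points on the latent
#'   scale defining the ordinal mRS90 categories 0-6.
#' @param sigma_mrs SD of the independent noise added to latent severity
#'   before thresholding into mRS90.
#' @param rater_noise Probability that a re-reading rater flips any one
#'   segment flag (used by [simulate_raters()]).
#' @param treatment_probs Probability weights for the APT/TPA/EVT labels.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed,
                       n = 130L,
                       p_origin = c(ica = 0.50, m1 = 0.40, m2 = 0.08, none = 0.02),
                       p_extend_distal = 0.92,
                       p_supra_only = 0.40,
                       p_infra_only = 0.15,
                       p_both_ica = 0.45,
                       p_aca = 0.25,
                       w_true = c(
                         ica = 3, m1_proximal = 2, m1_distal = 2,
                         aca = 1, m2_superior = 1, m2_inferior = 1
                       ),
                       sigma_latent = 1.0,
                       nihss_map = c(intercept = 8.4, slope = 1.0, sd = 2.5),
                       aspects_map = c(intercept = 10, slope = -0.7, sd = 1.2),
                       mrs_thresholds = c(3.9, 5.25, 6.3, 7.2, 8.1, 9.1),
                       sigma_mrs = 2.0,
                       rater_noise = 0.05,
                       treatment_probs = c(APT = 57, TPA = 20, EVT = 53) / 130) {
  if (missing(seed)) stop("sim_config: `seed` is required", call. = FALSE)
  cfg <- list(
    seed = as.integer(seed), n = as.integer(n),
    p_origin = p_origin, p_extend_distal = p_extend_distal,
    p_supra_only = p_supra_only, p_infra_only = p_infra_only,
    p_both_ica = p_both_ica, p_aca = p_aca,
    w_true = w_true, sigma_latent = sigma_latent,
    nihss_map = nihss_map, aspects_map = aspects_map,
    mrs_thresholds = mrs_thresholds, sigma_mrs = sigma_mrs,
    rater_noise = rater_noise, treatment_probs = treatment_probs
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid sim_config field `", field, "`: ", why, call. = FALSE)
  }
  if (is.na(cfg$seed)) fail("seed", "must be an integer")
  if (cfg$n < 10) fail("n", "cohort size must be >= 10")
  po <- cfg$p_origin
  if (!all(c("ica", "m1", "m2", "none") %in% names(po)) ||
    any(po < 0) || sum(po) <= 0) {
    fail("p_origin", "needs non-negative weights named ica/m1/m2/none")
  }
  cfg$p_origin <- po[c("ica", "m1", "m2", "none")] / sum(po)
  for (f in c(
    "p_extend_distal", "p_supra_only", "p_infra_only",
    "p_both_ica", "p_aca", "rater_noise"
  )) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      fail(f, "must be a probability in [0, 1]")
    }
  }
  ica_sum <- cfg$p_supra_only + cfg$p_infra_only + cfg$p_both_ica
  if (abs(ica_sum - 1) > 1e-8) {
    fail("p_supra_only/p_infra_only/p_both_ica", "must sum to 1")
  }
  wt_names <- c(
    "ica", "m1_proximal", "m1_distal", "aca", "m2_superior", "m2_inferior"
  )
  if (!all(wt_names %in% names(cfg$w_true)) || any(cfg$w_true < 0)) {
    fail("w_true", "needs non-negative weights for all six score items")
  }
  cfg$w_true <- cfg$w_true[wt_names]
  if (cfg$sigma_latent < 0) fail("sigma_latent", "must be >= 0")
  if (cfg$sigma_mrs < 0) fail("sigma_mrs", "must be >= 0")
  for (f in c("nihss_map", "aspects_map")) {
    if (length(cfg[[f]]) != 3L || cfg[[f]][3] < 0) {
      fail(f, "needs c(intercept, slope, sd) with sd >= 0")
    }
  }
  th <- cfg$mrs_thresholds
  if (length(th) != 6L || any(diff(th) <= 0)) {
    fail("mrs_thresholds", "needs 6 strictly increasing cut-points")
  }
  tp <- cfg$treatment_probs
  if (length(tp) != 3L || any(tp < 0) || sum(tp) <= 0) {
    fail("treatment_probs", "needs 3 non-negative weights")
  }
  cfg$treatment_probs <- tp / sum(tp)
  structure(cfg, class = "sim_config")
}

clamp_round <- function(x, lo, hi) {
  pmin(pmax(round(x), lo), hi)
}

#' Simulate a synthetic stroke cohort
#'
#' Draws `config$n` patients. Each patient receives an occlusion origin
#' (ICA, M1, M2 or none), distal propagation of involvement with
#' probability `p_extend_distal` per level, an ICA sub-pattern
#' (supraclinoid only / infraclinoid only / both) and possible ACA
#' involvement; latent severity is the weighted sum of involved score items
#' plus Gaussian noise, and NIHSS, ASPECTS, mRS0 and mRS90 are generated
#' from it. Mortality is implied by mRS90 = 6. Age, sex and treatment
#' labels are generated for realism but do not enter the outcome model.
#'
#' The result is deterministic given the config (including its seed); the
#' caller's RNG state is left untouched.
#'
#' @param config A [sim_config()].
#' @return A `simulated_cohort` tibble: the cohort CSV schema columns plus
#'   audit columns `origin` (generation pathway) and `latent` (hidden
#'   severity), with the generating config in attribute `"config"`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 1, n = 20))
#' dplyr::count(cohort, mrs90)
simulate_cohort <- function(config) {
  config <- validate_sim_config(unclass(config))
  n <- config$n
  with_preserved_seed({
    set.seed(config$seed)

    origin <- sample(
      c("ica", "m1", "m2", "none"), n,
      replace = TRUE, prob = config$p_origin
    )
    flags <- matrix(FALSE, n, 7L, dimnames = list(NULL, segment_names()))
    pe <- config$p_extend_distal

    for (i in seq_len(n)) {
      if (origin[i] == "ica") {
        pat <- sample(
          c("supra", "infra", "both"), 1L,
          prob = c(config$p_supra_only, config$p_infra_only, config$p_both_ica)
        )
        if (pat %in% c("infra", "both")) flags[i, "ica_infraclinoid"] <- TRUE
        if (pat %in% c("supra", "both")) flags[i, "ica_supraclinoid"] <- TRUE
        if (stats::runif(1) < config$p_aca) flags[i, "aca"] <- TRUE
        if (stats::runif(1) < pe) {
          flags[i, "m1_proximal"] <- TRUE
          if (stats::runif(1) < pe) {
            flags[i, "m1_distal"] <- TRUE
            flags[i, "m2_superior"] <- stats::runif(1) < pe
            flags[i, "m2_inferior"] <- stats::runif(1) < pe
          }
        }
      } else if (origin[i] == "m1") {
        flags[i, "m1_proximal"] <- TRUE
        if (stats::runif(1) < pe) {
          flags[i, "m1_distal"] <- TRUE
          flags[i, "m2_superior"] <- stats::runif(1) < pe
          flags[i, "m2_inferior"] <- stats::runif(1) < pe
        }
      } else if (origin[i] == "m2") {
        branch <- sample(c("m2_superior", "m2_inferior"), 1L)
        flags[i, branch] <- TRUE
      }
    }

    w <- config$w_true
    latent <- w[["ica"]] *
      (flags[, "ica_infraclinoid"] | flags[, "ica_supraclinoid"]) +
      w[["m1_proximal"]] * flags[, "m1_proximal"] +
      w[["m1_distal"]] * flags[, "m1_distal"] +
      w[["aca"]] * flags[, "aca"] +
      w[["m2_superior"]] * flags[, "m2_superior"] +
      w[["m2_inferior"]] * flags[, "m2_inferior"] +
      stats::rnorm(n, 0, config$sigma_latent)

    nm <- config$nihss_map
    nihss <- clamp_round(
      nm[[1]] + nm[[2]] * latent + stats::rnorm(n, 0, nm[[3]]), 0L, 42L
    )
    am <- config$aspects_map
    aspects <- clamp_round(
      am[[1]] + am[[2]] * latent + stats::rnorm(n, 0, am[[3]]), 0L, 10L
    )
    mrs90 <- findInterval(
      latent + stats::rnorm(n, 0, config$sigma_mrs), config$mrs_thresholds
    )
    mrs0 <- clamp_round(
      0.8 + 0.35 * latent + stats::rnorm(n, 0, 0.8), 0L, 5L
    )
    treatment <- sample(
      c("APT", "TPA", "EVT"), n,
      replace = TRUE, prob = config$treatment_probs
    )
    age <- clamp_round(stats::rnorm(n, 64.85, 14.14), 18L, 100L)
    sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.531, 0.469))

    out <- tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(n)),
      !!!as.data.frame(flags + 0L),
      nihss = as.integer(nihss),
      aspects = as.integer(aspects),
      mrs0 = as.integer(mrs0),
      mrs90 = as.integer(mrs90),
      treatment = treatment,
      age = as.integer(age),
      sex = sex,
      origin = origin,
      latent = latent
    )
    attr(out, "config") <- config
    class(out) <- c("simulated_cohort", class(out))
    out
  })
}

#' Simulate repeated rater readings
#'
#' Emulates independent re-reading of the angiograms: each rater flips each
#' segment flag of each patient with probability `rater_noise` and then
#' scores the perturbed status under both built-in schemes. With
#' `rater_noise = 0` all raters agree perfectly.
#'
#' @param cohort A cohort data frame with the segment flag columns.
#' @param rater_noise Per-segment flip probability (default: the generating
#'   config's value if present, else 0.05).
#' @param k_raters Number of raters, >= 2.
#' @param seed Integer seed for the flip process.
#' @return List of two n x k integer matrices, `cbs` and `mcbs`.
#' @export
simulate_raters <- function(cohort, rater_noise = NULL, k_raters = 2L, seed = 1L) {
  if (is.null(rater_noise)) {
    cfg <- attr(cohort, "config")
    rater_noise <- if (!is.null(cfg)) cfg$rater_noise else 0.05
  }
  stopifnot(k_raters >= 2L, rater_noise >= 0, rater_noise <= 1)
  flags <- as.matrix(tibble::as_tibble(cohort)[segment_names()]) == 1
  n <- nrow(flags)
  cbs <- builtin_scheme("cbs")
  mcbs <- builtin_scheme("mcbs")
  with_preserved_seed({
    set.seed(as.integer(seed))
    out <- list(
      cbs = matrix(NA_integer_, n, k_raters),
      mcbs = matrix(NA_integer_, n, k_raters)
    )
    for (r in seq_len(k_raters)) {
      flips <- matrix(stats::runif(n * 7L) < rater_noise, n, 7L)
      seen <- xor(flags, flips)
      colnames(seen) <- segment_names()
      for (i in seq_len(n)) {
        st <- stats::setNames(seen[i, ], segment_names())
        out$cbs[i, r] <- compute_score(st, cbs)$score
        out$mcbs[i, r] <- compute_score(st, mcbs)$score
      }
    }
    colnames(out$cbs) <- colnames(out$mcbs) <- paste0("rater", seq_len(k_raters))
    out
  })
}

#' Sweep the true ICA weight and measure the mCBS advantage
#'
#' For each candidate true ICA weight, simulates cohorts with that weight in
#' the latent-severity model, scores every cohort under both schemes, and
#' runs the paired DeLong comparison of the two disability AUCs. Reports,
#' per weight, the mean AUC difference (modified minus original), the mean
#' AUCs and the fraction of replicates rejecting equality at the 5% level.
#' When the truth gives ICA involvement no more weight than the original
#' scheme does, the mean difference should sit near zero; as the true ICA
#' weight grows, the ICA-weighted scheme should pull ahead.
#'
#' @param base_config A [sim_config()] to modify.
#' @param ica_weights Numeric vector of true ICA weights to try.
#' @param replicates Replicates per weight, >= 10.
#' @param seed Integer master seed; each replicate gets a derived sub-seed.
#' @return Tibble with one row per weight: `ica_weight`, `mean_auc_diff`,
#'   `mean_auc_mcbs`, `mean_auc_cbs`, `reject_frac`, `n_replicates`.
#' @export
weight_sweep <- function(base_config, ica_weights, replicates = 50L, seed = 1L) {
  stopifnot(replicates >= 10L)
  base_config <- validate_sim_config(unclass(base_config))
  # common random numbers: each replicate reuses the same sub-seed across
  # weights, so the sweep isolates the effect of the true ICA weight
  purrr::map_dfr(seq_along(ica_weights), function(wi) {
    w <- ica_weights[wi]
    res <- purrr::map_dfr(seq_len(replicates), function(r) {
      cfg <- unclass(base_config)
      cfg$w_true[["ica"]] <- w
      cfg$seed <- (as.integer(seed) + 104729L * r) %% 2147483629L
      cohort <- simulate_cohort(validate_sim_config(cfg))
      scored <- add_scores(cohort)
      lab <- dichotomize_outcomes(scored$mrs90, scored$nihss)$disability
      if (sum(lab) == 0L || sum(lab) == length(lab)) {
        return(tibble::tibble(
          delta = NA_real_, auc_a = NA_real_,
          auc_b = NA_real_, p = NA_real_
        ))
      }
      cmp <- tryCatch(
        delong_test(scored$mcbs, scored$cbs, lab),
        error = function(e) NULL # zero-variance report on a tied replicate
      )
      if (is.null(cmp)) {
        ra <- roc_curve(scored$mcbs, lab)
        rb <- roc_curve(scored$cbs, lab)
        return(tibble::tibble(
          delta = ra$auc - rb$auc, auc_a = ra$auc, auc_b = rb$auc,
          p = NA_real_
        ))
      }
      tibble::tibble(
        delta = cmp$delta, auc_a = cmp$auc_a, auc_b = cmp$auc_b,
        p = cmp$p_value
      )
    })
    res <- res[!is.na(res$delta), ]
    tibble::tibble(
      ica_weight = w,
      mean_auc_diff = mean(res$delta),
      mean_auc_mcbs = mean(res$auc_a),
      mean_auc_cbs = mean(res$auc_b),
      reject_frac = mean(res$p < 0.05, na.rm = TRUE),
      n_replicates = nrow(res)
    )
  })
}
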