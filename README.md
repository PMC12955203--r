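# clotburden

Segment-weighted clot burden scoring and prognostic evaluation for
anterior-circulation ischemic stroke.

In large-vessel-occlusion (LVO) stroke, the extent and location of thrombus
on vessel imaging (CTA or TOF-MRA) carry prognostic information. The **Clot
Burden Score (CBS)** summarizes this on a 10-point scale: starting from 10
(no thrombus), points are deducted per affected segment — 2 each for the
supraclinoid internal carotid artery (ICA), the proximal half of the MCA
trunk (M1) and the distal half of M1, and 1 each for the infraclinoid ICA,
the anterior cerebral artery (ACA) and each affected M2 branch — down to 0
for complete multisegment occlusion. Because ICA occlusion compromises
collateral supply out of proportion to its single-segment footprint, an
**ICA-weighted modification (mCBS)** replaces the two ICA items with a
single intracranial-ICA item deducting 3 points when thrombus involves
either ICA segment, keeping the 0–10 range.

This package is aimed at stroke researchers who want to score cohorts,
compare the prognostic value of the two schemes (or their own integer
variants), and stress-test the comparison methodology on fully synthetic
cohorts. It provides:

- **Scoring** — `builtin_scheme()`, `compute_score()`, `score_cohort()`,
  `add_scores()`, plus `scoring_scheme()` for user-defined deduction
  schemes.
- **Evaluation statistics**, implemented from first principles and verified
  against brute-force oracles in the test suite:
  tie-corrected Spearman rank correlation (`spearman_test()`,
  `stratified_spearman()`); empirical ROC curves with Mann–Whitney AUC
  \(P(S_{pos} < S_{neg}) + \tfrac12 P(S_{pos}=S_{neg})\) and DeLong
  structural-components variance (`roc_curve()`); the paired DeLong test
  for correlated AUCs (`delong_test()`); Youden-index criterion selection
  (`youden_index()`); two-way random-effects ICC(2,1) with the five-band
  interpretation scale (`icc()`, `icc_band()`); Wilcoxon rank-sum and
  Fisher exact tests; and an exploratory Hanley–McNeil power approximation
  for paired AUC differences (`auc_power_posthoc()`).
- **A synthetic cohort simulator** (`sim_config()`, `simulate_cohort()`,
  `simulate_raters()`, `weight_sweep()`) generating anatomically structured
  occlusion patterns, latent severity, and NIHSS/ASPECTS/mRS outcomes, so
  the whole score-versus-outcome pipeline runs without patient data.
- **I/O and orchestration** — cohort CSV reading with row-level validation
  and quarantine (`read_cohort()`), `run_evaluation()` producing a
  deterministic JSON report, ggplot2 `autoplot()`/`plot_score_by_outcome()`
  figures, and a thin CLI (`inst/cli/clotburden`) with `score`,
  `evaluate`, `simulate` and `sweep` subcommands.

Outcome dichotomies follow the usual clinical conventions: mortality is
mRS90 = 6, disability is mRS90 ≥ 2, severe stroke is admission NIHSS ≥ 15.
ROC positivity is oriented as `score ≤ c` (low score = heavy burden =
adverse outcome), matching how CBS criteria are reported.

## Worked example

```r
library(clotburden)

cohort <- simulate_cohort(sim_config(seed = 2026))   # 130 synthetic patients
scored <- add_scores(cohort)

spearman_test(scored$mcbs, scored$nihss)
#>      rho  p_value     n method
#>   -0.635 5.23e-16   130 t-approximation

lab <- dichotomize_outcomes(scored$mrs90, scored$nihss)$disability
r <- roc_curve(scored$mcbs, lab, positive_meaning = "disability")
r
#> <roc_result> disability: AUC 0.8976 (SE 0.0284, 95% CI 0.8419-0.9533), 88 cases / 42 controls
youden_index(r)
#>       j criterion sensitivity specificity
#>   0.633         2       0.705       0.929

delong_test(scored$mcbs, scored$cbs, lab)
#>   auc_a auc_b   delta     z p_value
#>   0.898 0.891 0.00649 0.818   0.413

ratings <- simulate_raters(cohort, rater_noise = 0.05, k_raters = 2, seed = 1)
icc(ratings$mcbs)
#> <icc_result> ICC(2,1) = 0.8824 (95% CI 0.8376-0.9154), very good agreement; n = 130 subjects, k = 2 raters
```

Reading the numbers: the modified score correlates strongly and negatively
with admission NIHSS (heavier clot burden, worse deficit); against 90-day
disability it discriminates with AUC ≈ 0.90, and the Youden-optimal rule
"mCBS ≤ 2" trades 70% sensitivity for 93% specificity. On this particular
cohort the paired DeLong test finds no significant AUC advantage of the
modified over the original scheme (single cohorts are noisy; the
`weight_sweep()` replication machinery exists for exactly this reason).
With 5% per-segment rater flip noise, inter-rater agreement lands in the
"very good" band.

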