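---
title: "Clot burden scoring and its prognostic evaluation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clot burden scoring and its prognostic evaluation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clotburden)
```

## The scoring model

Both built-in schemes are instances of one abstraction: a patient starts at
`max_score = 10` and loses a fixed integer deduction for every scheme item
whose trigger fires, where an item's trigger fires when thrombus is present
in *any* of its listed arterial segments. Seven unilateral
anterior-circulation segments are flagged per patient (infraclinoid ICA,
supraclinoid ICA, proximal M1, distal M1, ACA, superior M2, inferior M2);
partial and complete occlusions both count as presence, and a missing flag
makes the patient unscorable rather than silently zero.

The original scheme (CBS) deducts 2 points each for the supraclinoid ICA
and the two M1 halves, and 1 point each for the infraclinoid ICA, the ACA
and each M2 branch. The modified scheme (mCBS) raises the intracranial-ICA
deduction to 3 points.

**The ICA-merge decision.** A naive reading of "raise the ICA deduction to
3" while keeping a separate 1-point infraclinoid item would make the
deductions sum to 11 and break the stated 0–10 range. We therefore model
the modified scheme's ICA penalty as a *single* 3-point item triggered by
thrombus in either ICA segment. This preserves the 0–10 range and yields a
clean, exhaustively verifiable relation over all $2^7$ statuses: the two
schemes agree except on isolated-ICA patterns, where the modified score is
lower by 1 (supraclinoid only) or 2 (infraclinoid only). A consequence
worth stating explicitly is that under this construction the modified score
can never exceed the original score for the same patient, so score
*distributions* in which the modified scheme's median sits above the
original's cannot arise from these deduction rules; the package makes no
attempt to emulate such a pattern.

`scoring_scheme()` accepts user-defined integer variants (any positive
integer deductions, every segment covered by at least one item), which is
what the weight-sweep experiment uses.

## Evaluation statistics

All comparison statistics are implemented from first principles in R; the
test suite pins each one to an independent brute-force oracle
(pair-enumeration AUC, delete-one jackknife, exhaustive permutation and
hypergeometric enumeration) and, where available, to a second
implementation (`cor.test`, `wilcox.test`, `fisher.test`, `pROC`).

- **Spearman correlation** is the Pearson correlation of midranks
  (tie-corrected). For $n \ge 10$ the two-sided p-value uses the
  $t$-approximation with $n-2$ degrees of freedom; for $n \le 8$ the
  permutation null is enumerated exactly over all $n!$ orderings; at
  $n = 9$ (where $9! = 362{,}880$ correlations are wasteful but the
  $t$-approximation is still crude) a seeded Monte Carlo with 20,000 draws
  is used. Constant vectors are an error, not a silent `NA`.
- **ROC/AUC.** Low scores predict the adverse outcome, so positivity at
  criterion $c$ is `score <= c` and operating points are enumerated over
  all observed score values. The AUC is the Mann–Whitney statistic with the
  half-tie convention; it equals the trapezoidal area under the empirical
  curve identically, which the tests assert to $10^{-12}$. The variance is
  DeLong's structural-components estimator; the 95% CI is the normal
  interval truncated to $[0,1]$. Degenerate (single-class) outcomes raise
  an explicit error, which `run_evaluation()` converts into a degeneracy
  notice instead of a ROC section.
- **Paired AUC comparison** uses the paired DeLong construction:
  $\mathrm{var}(\Delta) = \mathrm{var}(V^{10}_a - V^{10}_b)/m +
  \mathrm{var}(V^{01}_a - V^{01}_b)/n$. Identical score vectors
  short-circuit to $z = 0, p = 1$; zero estimated variance with
  non-identical scores is reported as an error because the normal
  approximation is meaningless there. The grouped delete-one jackknife is
  algebraically equivalent and serves as the test oracle.
- **Youden criterion.** $J = \text{sens} + \text{spec} - 1$ maximized over
  operating points; ties break toward the smallest criterion, i.e. the more
  specific rule, matching the convention of quoting "≤ c" criteria with
  100% specificity where available.
- **ICC.** Inter-rater reliability uses ICC(2,1): two-way random effects,
  absolute agreement, single rater — the natural model when raters are
  interchangeable readers of the same angiograms and systematic rater
  offsets should count against agreement. The CI is the McGraw–Wong
  F-based interval. Interpretation bands: poor (< 0.20), fair (0.21–0.40),
  moderate (0.41–0.60), good (0.61–0.80), very good (0.81–1.0); the
  implementation treats the band edges as half-open intervals so every
  value in $[-1, 1]$ maps to exactly one band. Perfect agreement (zero
  residual and rater variance) returns a degenerate CI of $(1, 1)$; zero
  between-subject variance is an explicit error.
- **Wilcoxon rank-sum** enumerates the exact null over all
  $\binom{n_x+n_y}{n_x}$ assignments when the pooled sample is at most 12
  and tie-free, else uses the normal approximation with tie and continuity
  correction. **Fisher's exact test** sums hypergeometric probabilities no
  larger than the observed table's (with the customary $1 + 10^{-7}$
  relative tolerance) and reports the sample cross-ratio odds ratio with
  `Inf`/`0` conventions for zero cells.
- **Post-hoc power** for a paired AUC difference uses Hanley–McNeil
  variances and a user-supplied correlation between the two AUC estimates
  (default 0.5). This is deliberately labelled exploratory: the result is
  quite sensitive to the assumed correlation, which is rarely known, so it
  should be read as a sensitivity analysis, not an inference.
- **Multiple testing:** none. Every p-value is reported raw, matching
  standard practice for this kind of single-cohort prognostic comparison.

`run_evaluation()` applies complete-case exclusion at the I/O boundary:
rows with illegal codes or a missing 90-day outcome are quarantined with
per-row reasons, and the report's `meta` section accounts for every
excluded row. Report floats are half-even rounded (4 decimals for
statistics, 2 for percentages on the 0–100 scale) so identical cohorts
serialize to byte-identical JSON.

## The synthetic cohort generator

The simulator exists so the whole pipeline — scoring, correlation, ROC,
paired tests, reliability — can be exercised end-to-end and its operating
characteristics studied under a *known* truth. Per patient:

1. **Occlusion origin** is drawn from `p_origin` over
   \{ICA, M1, M2, none\} (defaults 0.50/0.40/0.08/0.02).
2. **Distal propagation:** involvement extends one level distally with
   probability `p_extend_distal = 0.92` per step (ICA → proximal M1 →
   distal M1 → each M2 branch independently). M1-origin occlusions start
   at the proximal trunk; M2-origin occlusions affect one random branch.
   This makes patterns anatomically coherent: distal M1 involvement
   without proximal involvement never arises on the ICA pathway, and the
   generation pathway is kept as an audit column.
3. **ICA sub-pattern:** supraclinoid only / infraclinoid only / both with
   probabilities 0.40/0.15/0.45, plus ACA involvement with probability
   0.25 given ICA occlusion.
4. **Latent severity** $L$ is a weighted sum of involved score items plus
   $N(0, \sigma_{latent})$ noise. The weights `w_true` are per *item*,
   with the two ICA flags pooled into a single `ica` weight — mirroring
   the scheme structure, and making "the true ICA weight" a single dial
   for the sweep experiment. The default weight vector (ICA 3, M1 halves 2
   each, ACA and M2 branches 1 each) is proportional to the modified
   scheme's deductions, i.e. an ICA-heavy truth.
5. **Clinical scales:** NIHSS $= \mathrm{clamp}(\mathrm{round}(8.4 + 1.0 L
   + N(0, 2.5)), 0, 42)$; ASPECTS $= \mathrm{clamp}(\mathrm{round}(10 -
   0.7 L + N(0, 1.2)), 0, 10)$; mRS90 is the ordinal category of
   $L + N(0, 2)$ against six increasing thresholds, with mortality implied
   by mRS90 = 6. Age (normal, 64.85 ± 14.14), sex (53.1% male) and
   treatment labels (APT/TPA/EVT in proportions 57:20:53) are generated
   for realism only and never enter the outcome model.

Defaults were chosen once to be anatomically plausible and to land the
marginal structure of a typical severe MCA-territory LVO cohort of 130 —
mean admission NIHSS near 14.8, roughly 22% dead and 64% disabled at 90
days, original-score median around 4 — and then frozen;
`scripts/calibrate-simulator.R` re-audits those targets over replicate
cohorts. Everything is reproducible bit-for-bit from the config (seed
included), and all generator code restores the caller's RNG state.

**What the simulator does not emulate.** Real cohorts have correlated
comorbidity, treatment selection by severity, collateral status, and
measurement error in NIHSS and mRS themselves; the generator has none of
these. Passing tests therefore demonstrate that the *methodology* behaves
correctly under a controlled truth (direction recovery, calibrated nulls,
reliability degradation with rater noise) — not that any particular
clinical effect size will replicate in patients.

**Rater simulation** flips each segment flag independently with
probability `rater_noise` per rater before re-scoring, which yields exact
agreement (ICC = 1) at zero noise and progressively degraded agreement as
noise grows.

**The weight sweep** varies the true ICA weight, simulates replicate
cohorts per value, and reports the mean paired difference in disability
AUC (modified minus original) with the fraction of replicates rejecting
equality. Replicates reuse the same sub-seed across weights (common random
numbers), so the sweep isolates the weight effect rather than re-drawing
independent noise per weight. Under a truth proportional to the original
deductions with no isolated-ICA patterns the two schemes coincide patient
by patient and the difference is identically zero — a useful built-in
null.

## Problem sizes and numerical choices

The test suite runs the exhaustive $2^7$ scheme audit, oracle comparisons
on 20–25 random fixtures per statistic (n = 25–40 per fixture), simulation
checks at 200 replicates of n = 130 (direction and null of the AUC
difference), a 10,000-patient monotonicity audit, a 100-replicate
null-ICC study at n = 500, and a 100-replicate-per-weight sweep — sizes
chosen to make the Monte Carlo margins comfortably smaller than the
effects being asserted while keeping the default suite under a minute of
compute. Tolerances: $10^{-12}$ where two exact algorithms must agree
(trapezoid vs Mann–Whitney, enumeration vs enumeration), $10^{-6}$ where
an oracle is algebraically equivalent but numerically distinct (jackknife
vs structural components, quadrature vs closed form).

Tie-breaking and degenerate-input behaviour are part of the contract:
Youden ties go to the smallest criterion; identical paired scores give
$p = 1$; single-class outcomes, constant vectors, empty groups, zero
margins and zero between-subject variance all raise named errors (or
quarantine/notice entries at the pipeline level) rather than propagating
`NaN`.

## Known limitations

- Scoring is unilateral by construction; bilateral disease and
  posterior-circulation variants are out of scope.
- The modified scheme's published description is ambiguous about the
  infraclinoid item; the merge adopted here is one defensible resolution
  (see the ICA-merge discussion above) and its pointwise consequence —
  modified ≤ original — should be kept in mind when comparing score
  distributions.
- DeLong CIs are normal-theory; no bootstrap alternative is provided.
- The power calculation reconstructs nothing: without a stated method and
  correlation it cannot, and it says so.
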