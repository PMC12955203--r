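Package: clotburden
Title: Clot Burden Scoring and Prognostic Evaluation for Anterior-Circulation Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Clot Burden Score (CBS) and an ICA-weighted
    modification (mCBS) as segment-weighted deduction schemes for
    anterior-circulation large-vessel-occlusion stroke, together with the
    statistical battery used to compare prognostic scores against clinical
    outcomes: tie-corrected Spearman rank correlation, empirical ROC curves
    with Mann-Whitney AUC and DeLong variance, paired DeLong tests, Youden
    index criterion selection, two-way random-effects intraclass correlation
    for inter-rater reliability, Wilcoxon rank-sum and Fisher exact tests,
    and a post-hoc power approximation for correlated AUC differences. A
    seeded synthetic cohort simulator with anatomically structured occlusion
    patterns and latent-severity outcome generation makes the full
    score-versus-outcome comparison reproducible without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
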