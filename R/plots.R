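#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an empirical ROC curve
#'
#' Step plot of sensitivity against 1 - specificity with the chance
#' diagonal and the AUC in the subtitle.
#'
#' @param object A `roc_result` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  op <- object$operating_points
  df <- tibble::tibble(
    fpr = c(0, 1 - op$specificity, 1),
    tpr = c(0, op$sensitivity, 1)
  ) |> dplyr::arrange(.data$fpr, .data$tpr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(
      intercept = 0, slope = 1, linetype = "dashed", colour = "grey60"
    ) +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = paste("ROC:", object$positive_meaning),
      subtitle = sprintf(
        "AUC %.3f (95%% CI %.3f-%.3f), %d cases / %d controls",
        object$auc, object$ci95[1], object$ci95[2],
        object$n_pos, object$n_neg
      )
    ) +
    ggplot2::theme_minimal()
}

#' Violin plot of score distributions by 90-day outcome
#'
#' Mirrors the customary presentation of clot-burden scores stratified by
#' dichotomized 90-day functional outcome (mRS90 0-1 versus 2-6).
#'
#' @param scored Data frame containing the score column and `mrs90`.
#' @param score_col Score column name, `"cbs"` or `"mcbs"` typically.
#' @return A ggplot.
#' @export
plot_score_by_outcome <- function(scored, score_col = "cbs") {
  scored <- tibble::as_tibble(scored)
  stopifnot(score_col %in% names(scored), "mrs90" %in% names(scored))
  df <- tibble::tibble(
    score = scored[[score_col]],
    outcome = factor(
      ifelse(scored$mrs90 >= 2, "mRS90 2-6", "mRS90 0-1"),
      levels = c("mRS90 0-1", "mRS90 2-6")
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$outcome, y = .data$score, fill = .data$outcome
  )) +
    ggplot2::geom_violin(alpha = 0.7, adjust = 1.2) +
    ggplot2::geom_jitter(width = 0.08, height = 0.12, size = 0.8, alpha = 0.5) +
    ggplot2::scale_y_continuous(breaks = 0:10, limits = c(-0.5, 10.5)) +
    ggplot2::labs(
      x = NULL, y = toupper(score_col),
      title = paste(toupper(score_col), "by 90-day outcome")
    ) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
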