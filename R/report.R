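#' Validate a labelled cohort end to end
#'
#' One-call pipeline mirroring the validation analysis: score the raw
#' cohort, build the per-group band table, and evaluate the requested
#' binary contrast (ROC, AUC, integer-threshold sensitivity/specificity
#' table, and the selected threshold under the sensitivity/specificity
#' rule).
#'
#' @param cohort raw cohort tibble containing both groups.
#' @param positive,negative label values defining the contrast, e.g.
#'   `"FM"` vs `"NON_FM"` or `"ACR_POS"` vs `"ACR_NEG"`.
#' @param sens_target,spec_min threshold-selection rule (defaults 0.95 and
#'   0.50).
#' @return an `fd_evaluation` (see [evaluate_scores()]).
#' @examples
#' cohort <- dplyr::bind_rows(
#'   generate_cohort(group_config("FM", n = 60, mu = 1.5, seed = 1)),
#'   generate_cohort(group_config("NON_FM", n = 60, mu = -0.5, seed = 2)))
#' validate_cohort(cohort, "FM", "NON_FM")
#' @export
validate_cohort <- function(cohort, positive, negative,
                            sens_target = 0.95, spec_min = 0.50) {
  scored <- score_responses(cohort)
  evaluate_scores(scored, positive, negative,
                  sens_target = sens_target, spec_min = spec_min)
}

#' Score distribution plot for a scored cohort
#'
#' Per-group histogram of the 0-9 score with the decision-band boundaries
#' (between 3/4 and 5/6) marked; missing scores are dropped.
#'
#' @param scored output of [score_responses()].
#' @return a ggplot.
#' @export
plot_score_distribution <- function(scored) {
  d <- scored[!is.na(scored$score), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, fill = .data$label)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::geom_vline(xintercept = c(3.5, 5.5), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_x_continuous(breaks = 0:9, limits = c(-0.5, 9.5)) +
    ggplot2::labs(x = "Screening score", y = "Respondents", fill = NULL) +
    ggplot2::theme_minimal()
}
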