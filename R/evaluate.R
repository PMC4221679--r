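#' Band table: descriptive score summary per cohort group
#'
#' Reproduces the standard validation-report layout for a scored cohort:
#' per group, the number of non-missing scores, mean, SD, median, quartiles,
#' min-max, and the count and percentage of respondents in each decision
#' band. Missing scores are excluded from every percentage (and counted in
#' `n_missing`).
#'
#' @param scored tibble with `score` and a grouping column (default
#'   `label`); typically the output of [score_responses()].
#' @param by name of the grouping column.
#' @return tibble with one row per group: `n_total`, `n`, `n_missing`,
#'   `mean`, `sd`, `median`, `q1`, `q3`, `min`, `max`, `n_low/mid/high`,
#'   `pct_low/mid/high`.
#' @examples
#' scores <- tibble::tibble(label = rep(c("FM", "NON_FM"), c(5, 5)),
#'                          score = c(9, 8, 7, 6, 2, 1, 2, 3, 6, 5))
#' band_table(scores)
#' @export
band_table <- function(scored, by = "label") {
  scored |>
    dplyr::group_by(group = .data[[by]]) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n = sum(!is.na(.data$score)),
      n_missing = sum(is.na(.data$score)),
      mean = mean(.data$score, na.rm = TRUE),
      sd = sd(.data$score, na.rm = TRUE),
      median = median(.data$score, na.rm = TRUE),
      q1 = quantile(.data$score, 0.25, na.rm = TRUE, names = FALSE),
      q3 = quantile(.data$score, 0.75, na.rm = TRUE, names = FALSE),
      min = suppressWarnings(min(.data$score, na.rm = TRUE)),
      max = suppressWarnings(max(.data$score, na.rm = TRUE)),
      n_low = sum(.data$score <= 3, na.rm = TRUE),
      n_mid = sum(.data$score >= 4 & .data$score <= 5, na.rm = TRUE),
      n_high = sum(.data$score >= 6, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pct_low = 100 * .data$n_low / .data$n,
      pct_mid = 100 * .data$n_mid / .data$n,
      pct_high = 100 * .data$n_high / .data$n
    )
}

#' Evaluate a scored cohort against a binary contrast
#'
#' Runs the full model-evaluation step on a scored, labelled cohort:
#' excludes missing scores, builds the integer-threshold ROC curve with its
#' AUC, computes sensitivity/specificity at every threshold, applies the
#' threshold-selection rule, and attaches the per-group band table.
#'
#' @param scored tibble with `score` and `label` columns (output of
#'   [score_responses()] or [compute_score()]).
#' @param positive,negative label values defining the contrast.
#' @param sens_target,spec_min threshold-selection rule passed to
#'   [select_threshold()].
#' @return list of class `fd_evaluation`: `roc` (`fd_roc`), `auc`,
#'   `thresholds` (sens/spec table), `selected` (chosen threshold row),
#'   `bands` (band table for the two groups).
#' @export
evaluate_scores <- function(scored, positive, negative,
                            sens_target = 0.95, spec_min = 0.50) {
  pos <- scored$score[scored$label == positive]
  neg <- scored$score[scored$label == negative]
  if (!length(pos[!is.na(pos)]) || !length(neg[!is.na(neg)])) {
    abort("a class is empty after excluding missing scores",
          class = "fd_contract_error")
  }
  curve <- roc_curve(pos, neg)
  bands <- band_table(scored[scored$label %in% c(positive, negative), ])
  structure(list(
    positive = positive, negative = negative,
    roc = curve, auc = curve$auc, thresholds = curve$points,
    selected = select_threshold(curve, sens_target, spec_min),
    bands = bands
  ), class = "fd_evaluation")
}

#' @export
print.fd_evaluation <- function(x, ...) {
  cat(sprintf("Evaluation: %s vs %s, AUC = %.3f\n",
              x$positive, x$negative, x$auc))
  cat(sprintf("Selected threshold %d (sens %.1f%%, spec %.1f%%%s)\n",
              x$selected$threshold, 100 * x$selected$sensitivity,
              100 * x$selected$specificity,
              if (x$selected$feasible) "" else "; rule infeasible"))
  cat("\nBand table:\n")
  print(as.data.frame(x$bands), digits = 3)
  cat("\nThreshold table:\n")
  print(as.data.frame(x$thresholds), digits = 3)
  invisible(x)
}

#' Sensitivity and specificity of a score cut-off
#'
#' Classifies a respondent positive when `score >= cutoff` and reports the
#' operating characteristics on the two groups, excluding missing scores.
#'
#' @param scores_pos,scores_neg score vectors for the two groups.
#' @param cutoff integer cut-off (default 6, the referral threshold).
#' @return tibble with `cutoff`, `sensitivity`, `specificity` (proportions).
#' @export
cutoff_performance <- function(scores_pos, scores_neg, cutoff = 6) {
  scores_pos <- scores_pos[!is.na(scores_pos)]
  scores_neg <- scores_neg[!is.na(scores_neg)]
  tibble(cutoff = cutoff,
         sensitivity = mean(scores_pos >= cutoff),
         specificity = mean(scores_neg < cutoff))
}
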