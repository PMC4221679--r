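#' ROC curve over integer score thresholds
#'
#' Builds the receiver operating characteristic of an integer score
#' (support 0-9) for separating a positive from a negative group. A
#' respondent is classified positive when `score >= t`; candidate
#' thresholds are the integers 0-10 (the score support plus one), so the
#' curve runs from (1, 1) at `t = 0` to (0, 0) at `t = 10` in
#' (1 - specificity, sensitivity) space. The AUC is the trapezoidal area
#' under that polyline, which for this construction equals the
#' Mann-Whitney concordance probability
#' `(#\{pos > neg\} + #\{pos = neg\}/2) / (n_pos * n_neg)`.
#'
#' @param scores_pos,scores_neg integer score vectors for the positive and
#'   negative groups; missing scores must be excluded beforehand.
#' @param thresholds candidate thresholds; defaults to the integers 0-10
#'   when all scores lie on the 0-9 grid, otherwise to the observed score
#'   values plus one point above the maximum.
#' @return an object of class `fd_roc`: list with `points` (tibble of
#'   `threshold`, `sensitivity`, `specificity`), `auc`, `n_pos`, `n_neg`.
#' @examples
#' roc_curve(c(7, 8, 9), c(1, 2, 3))$auc  # 1
#' @export
roc_curve <- function(scores_pos, scores_neg, thresholds = NULL) {
  scores_pos <- scores_pos[!is.na(scores_pos)]
  scores_neg <- scores_neg[!is.na(scores_neg)]
  if (!length(scores_pos) || !length(scores_neg)) {
    abort("both groups need at least one non-missing score",
          class = "fd_contract_error")
  }
  if (is.null(thresholds)) {
    all_scores <- c(scores_pos, scores_neg)
    on_grid <- all(all_scores == round(all_scores)) &&
      all(all_scores >= 0 & all_scores <= 9)
    thresholds <- if (on_grid) 0:10 else {
      u <- sort(unique(all_scores))
      c(u, max(u) + 1)
    }
  }
  n_pos <- length(scores_pos)
  n_neg <- length(scores_neg)
  count_pos <- vapply(thresholds, function(t) sum(scores_pos >= t),
                      numeric(1))
  count_neg <- vapply(thresholds, function(t) sum(scores_neg >= t),
                      numeric(1))
  points <- tibble(
    threshold = thresholds,
    sensitivity = count_pos / n_pos,
    specificity = 1 - count_neg / n_neg
  )
  ## trapezoid over (1 - spec, sens): the numerator is accumulated in
  ## integer counts and divided once, so the area is the exact rational
  ## sum_i (fpr_i - fpr_{i+1}) * (tpr_i + tpr_{i+1}) / 2 and coincides
  ## bit for bit with the Mann-Whitney concordance statistic
  o <- order(count_neg, count_pos)  # increasing false- then true-positive count
  cp <- count_pos[o]
  cn <- count_neg[o]
  auc <- sum(diff(cn) * (head(cp, -1) + cp[-1])) / (2 * n_pos * n_neg)
  structure(list(points = points, auc = auc,
                 n_pos = length(scores_pos), n_neg = length(scores_neg)),
            class = "fd_roc")
}

#' Mann-Whitney concordance probability
#'
#' Tie-corrected probability that a random positive outscores a random
#' negative; the pairwise identity the trapezoidal AUC must reproduce.
#'
#' @param scores_pos,scores_neg score vectors (no `NA`).
#' @return concordance in `[0, 1]`.
#' @export
concordance_auc <- function(scores_pos, scores_neg) {
  cmp <- outer(scores_pos, scores_neg, "-")
  (sum(cmp > 0) + sum(cmp == 0) / 2) / length(cmp)
}

#' Select a score threshold under a sensitivity/specificity rule
#'
#' Implements the published selection rule: among thresholds whose
#' sensitivity meets the target (default 95%) and whose specificity is at
#' least the floor (default 50%), return the one with the highest
#' specificity, breaking ties toward the higher threshold. If no threshold
#' satisfies both constraints, the result is flagged infeasible and carries
#' the best-specificity point among those still meeting the sensitivity
#' target (which always exists on an integer grid that includes a
#' classify-everyone threshold).
#'
#' @param curve an `fd_roc` object.
#' @param sens_target minimum sensitivity (default 0.95).
#' @param spec_min minimum specificity (default 0.50).
#' @return tibble with one row: `threshold`, `sensitivity`, `specificity`,
#'   `feasible`.
#' @export
select_threshold <- function(curve, sens_target = 0.95, spec_min = 0.50) {
  stopifnot(inherits(curve, "fd_roc"))
  pts <- curve$points
  sens_ok <- pts$sensitivity >= sens_target
  both_ok <- sens_ok & pts$specificity >= spec_min
  pick <- function(idx) {
    cand <- pts[idx, ]
    cand <- cand[cand$specificity == max(cand$specificity), ]
    cand[which.max(cand$threshold), ]
  }
  if (any(both_ok)) {
    best <- pick(both_ok)
    feasible <- TRUE
  } else {
    best <- pick(sens_ok)
    feasible <- FALSE
  }
  tibble(threshold = best$threshold, sensitivity = best$sensitivity,
         specificity = best$specificity, feasible = feasible)
}

#' @export
print.fd_roc <- function(x, ...) {
  cat(sprintf("ROC over integer thresholds: AUC = %.3f (n+ = %d, n- = %d)\n",
              x$auc, x$n_pos, x$n_neg))
  print(x$points, n = nrow(x$points))
  invisible(x)
}

#' Tidy the threshold table of an ROC curve
#' @param x an `fd_roc` object.
#' @param ... unused.
#' @return tibble of `threshold`, `sensitivity`, `specificity`.
#' @export
tidy.fd_roc <- function(x, ...) x$points

#' One-row AUC summary of an ROC curve
#' @param x an `fd_roc` object.
#' @param ... unused.
#' @return tibble with `auc`, `n_pos`, `n_neg`.
#' @export
glance.fd_roc <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Plot an ROC curve
#'
#' @param object an `fd_roc` object.
#' @param ... unused.
#' @return a ggplot of sensitivity against 1 - specificity with the chance
#'   diagonal.
#' @export
autoplot.fd_roc <- function(object, ...) {
  d <- object$points[order(1 - object$points$specificity), ]
  ggplot2::ggplot(d, ggplot2::aes(x = 1 - .data$specificity,
                                  y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.2f", object$auc)) +
    ggplot2::theme_minimal()
}
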