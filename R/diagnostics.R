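#' Odds ratio with Woolf confidence interval for a 2x2 table
#'
#' Cross-product odds ratio `(a*d)/(b*c)` for the table
#' (a = item 1 & positive, b = item 1 & negative, c = item 0 & positive,
#' d = item 0 & negative), with the large-sample log interval
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Zero cells are
#' handled by the Haldane-Anscombe correction (+0.5 to every cell) so the
#' estimate and interval stay finite for rare items.
#'
#' @param a,b,c,d non-negative cell counts.
#' @param correction `"haldane"` (add 0.5 to all cells when any is zero) or
#'   `"none"`.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return tibble with `or`, `ci_low`, `ci_high`, `corrected`.
#' @examples
#' odds_ratio_2x2(60, 40, 30, 70)  # OR 3.5, CI about (1.95, 6.29)
#' @export
odds_ratio_2x2 <- function(a, b, c, d, correction = c("haldane", "none"),
                           conf_level = 0.95) {
  correction <- match.arg(correction)
  cells <- c(a, b, c, d)
  if (any(cells < 0)) abort("cell counts must be non-negative")
  corrected <- FALSE
  if (any(cells == 0) && correction == "haldane") {
    cells <- cells + 0.5
    corrected <- TRUE
  }
  if (any(cells == 0)) {
    return(tibble(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  corrected = corrected))
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(or = or,
         ci_low = exp(log(or) - z * se),
         ci_high = exp(log(or) + z * se),
         corrected = corrected)
}

#' Per-item screening diagnostics: missing percentage and odds ratio
#'
#' For each coded item, computes the percentage of missing responses over
#' the cohort and, from the 2x2 table of complete responses against the
#' binary group label, the odds ratio with its 95% confidence interval. An
#' interval excluding 1 marks the item as significantly discriminating
#' between the groups; `degenerate` flags items that are all-missing or
#' constant (no usable table), which are reported rather than raised.
#'
#' @param items tibble of coded items with a `label` column
#'   (see [code_items()]); item values 0/1/`NA`.
#' @param positive,negative the two label values defining the contrast
#'   (defaults `ACR_POS` vs `ACR_NEG`).
#' @param item_cols which columns are items (default [item_names()]
#'   intersected with what is present).
#' @param correction zero-cell rule passed to [odds_ratio_2x2()].
#' @return tibble with one row per item: `item`, `missing_pct`, `or`,
#'   `ci_low`, `ci_high`, `significant`, `degenerate`.
#' @export
item_diagnostics <- function(items, positive = "ACR_POS",
                             negative = "ACR_NEG",
                             item_cols = NULL,
                             correction = "haldane") {
  item_cols <- item_cols %||% intersect(item_names(), names(items))
  if (!length(item_cols)) abort("no item columns found")
  keep <- items$label %in% c(positive, negative)
  if (!any(keep)) abort("no rows with the requested labels")
  items <- items[keep, , drop = FALSE]
  pos <- items$label == positive

  purrr::map_dfr(item_cols, function(j) {
    x <- items[[j]]
    missing_pct <- 100 * mean(is.na(x))
    obs <- !is.na(x)
    a <- sum(x == 1 & pos, na.rm = TRUE)
    b <- sum(x == 1 & !pos, na.rm = TRUE)
    cc <- sum(x == 0 & pos, na.rm = TRUE)
    d <- sum(x == 0 & !pos, na.rm = TRUE)
    degenerate <- !any(obs) || length(unique(x[obs])) < 2L
    or_row <- if (degenerate) {
      tibble(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
             corrected = FALSE)
    } else {
      odds_ratio_2x2(a, b, cc, d, correction = correction)
    }
    tibble(item = j, missing_pct = missing_pct,
           or = or_row$or, ci_low = or_row$ci_low, ci_high = or_row$ci_high,
           significant = !degenerate & !is.na(or_row$ci_low) &
             (or_row$ci_low > 1 | or_row$ci_high < 1),
           degenerate = degenerate)
  })
}
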