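#' Iterative multi-criteria item reduction
#'
#' Re-implements the item-selection loop used to build the discriminant
#' model: at each pass the current item set is diagnosed (per-item missing
#' percentage, odds ratio with 95% CI) and refitted by PLS-DA (VIP), and
#' one failing item is dropped. Criteria are evaluated in a fixed order —
#' missing percentage above the cap, then a confidence interval straddling
#' 1, then VIP below the floor — and among the failures of the first
#' violated criterion the item with the lowest VIP is dropped (ties: higher
#' missing percentage, then lexicographic id). Items carrying a clinical
#' flag are never dropped: expert-retained items are inputs, not inferred,
#' and an override is recorded in the trace instead. The loop stops when
#' every retained unflagged item passes all criteria.
#'
#' Every decision is logged in a trace (one row per event with the
#' triggering criterion and the values that fired it), so any assumed
#' reduction sequence is explicit and replayable.
#'
#' @param items coded-item tibble with a `label` column (see
#'   [code_items()]).
#' @param positive,negative label values defining the development contrast.
#' @param missing_cap maximum tolerated per-item missing percentage
#'   (default 15, just above the highest rate observed in practice).
#' @param vip_floor minimum VIP (default 1, the conventional importance
#'   cut).
#' @param clinical_flags character vector of item ids retained on clinical
#'   grounds regardless of their statistics.
#' @param ncomp PLS-DA components (default 2; reduced automatically when
#'   the remaining items cannot support it).
#' @param item_cols candidate item columns (default: the nine score items
#'   present in `items`).
#' @return object of class `fd_model`: `items` (retained ids), `trace`
#'   (tibble of decisions), `auc` (development AUC of the retained-item sum
#'   score), `diagnostics`, `vip`, `fit` (final `fd_plsda`).
#' @export
reduce_items <- function(items, positive = "ACR_POS", negative = "ACR_NEG",
                         missing_cap = 15, vip_floor = 1,
                         clinical_flags = character(), ncomp = 2,
                         item_cols = NULL) {
  current <- item_cols %||% intersect(item_names(), names(items))
  if (!length(current)) abort("no candidate items")
  keep_rows <- items$label %in% c(positive, negative)
  items <- items[keep_rows, , drop = FALSE]
  y <- items$label == positive

  trace <- list()
  step <- 0L
  overridden <- character()

  repeat {
    step <- step + 1L
    diag <- item_diagnostics(items, positive, negative, item_cols = current)
    fit <- plsda_fit_capped(items[, current, drop = FALSE], y, ncomp)
    vip <- fit$vip[diag$item]
    diag$vip <- as.numeric(vip)

    fails <- list(
      missing = diag$item[diag$missing_pct > missing_cap],
      or = diag$item[!diag$significant | diag$degenerate],
      vip = diag$item[!is.na(diag$vip) & diag$vip < vip_floor]
    )
    dropped <- FALSE
    for (criterion in names(fails)) {
      failing <- fails[[criterion]]
      if (!length(failing)) next
      flagged <- intersect(failing, clinical_flags)
      for (it in setdiff(flagged, overridden)) {
        trace[[length(trace) + 1L]] <- trace_row(
          step, "clinical override", it, criterion, diag)
        overridden <- c(overridden, it)
      }
      failing <- setdiff(failing, clinical_flags)
      if (!length(failing)) next
      ## drop the lowest-VIP failure; ties -> higher missing %, then id
      d <- diag[diag$item %in% failing, ]
      d <- d[order(d$vip, -d$missing_pct, d$item), ]
      victim <- d$item[1]
      trace[[length(trace) + 1L]] <- trace_row(step, "drop", victim,
                                               criterion, diag)
      current <- setdiff(current, victim)
      if (!length(current)) {
        cnd <- rlang::error_cnd("fd_empty_model_error",
          message = "reduction criteria eliminated every item",
          trace_table = dplyr::bind_rows(trace))
        rlang::cnd_signal(cnd)
      }
      dropped <- TRUE
      break
    }
    if (!dropped) {
      trace[[length(trace) + 1L]] <- tibble(
        step = step, action = "stop", item = NA_character_,
        criterion = NA_character_, missing_pct = NA_real_, or = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, vip = NA_real_)
      break
    }
  }

  ## development AUC of the retained-item sum score (complete items only)
  m <- as.matrix(items[, current, drop = FALSE])
  sums <- ifelse(rowSums(is.na(m)) == 0L, rowSums(m), NA_real_)
  auc <- roc_curve(sums[y], sums[!y])$auc

  structure(list(
    items = current, trace = dplyr::bind_rows(trace), auc = auc,
    diagnostics = diag, vip = fit$vip, fit = fit,
    criteria = list(missing_cap = missing_cap, vip_floor = vip_floor,
                    clinical_flags = clinical_flags, ncomp = ncomp)
  ), class = "fd_model")
}

trace_row <- function(step, action, item, criterion, diag) {
  d <- diag[diag$item == item, ]
  tibble(step = step, action = action, item = item, criterion = criterion,
         missing_pct = d$missing_pct, or = d$or, ci_low = d$ci_low,
         ci_high = d$ci_high, vip = d$vip)
}

## fit with as many components as the item set supports, up to ncomp
plsda_fit_capped <- function(x, y, ncomp) {
  k <- min(ncomp, ncol(x))
  repeat {
    fit <- tryCatch(plsda_fit(x, y, ncomp = k),
                    fd_rank_error = function(e) NULL)
    if (!is.null(fit) || k == 1L) break
    k <- k - 1L
  }
  if (is.null(fit)) abort("no PLS-DA component extractable from items")
  fit
}

#' @export
print.fd_model <- function(x, ...) {
  cat(sprintf("Reduced model: %d item(s) retained, development AUC = %.3f\n",
              length(x$items), x$auc))
  cat("  ", paste(x$items, collapse = ", "), "\n")
  drops <- x$trace[x$trace$action == "drop", ]
  if (nrow(drops)) {
    cat("Dropped:", paste(sprintf("%s (%s)", drops$item, drops$criterion),
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' Replay a reduction trace against an initial item set
#'
#' Applies the drop decisions of a trace, in order, to the starting item
#' set; used to confirm a recorded reduction is self-consistent.
#'
#' @param trace trace tibble from an `fd_model`.
#' @param initial_items starting item ids.
#' @return character vector of retained items after replay.
#' @export
replay_trace <- function(trace, initial_items) {
  drops <- trace$item[trace$action == "drop"]
  setdiff(initial_items, drops)
}
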