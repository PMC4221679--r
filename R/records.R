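#' Build a single questionnaire response record
#'
#' A cohort is a tibble with one row per respondent. Multi-select answers
#' (`q1_areas`, `q3_pain_kinds`, `q6_symptoms`) are list-columns holding a
#' character vector of ticked tokens; a zero-length vector means the question
#' was answered with nothing ticked ("none apply"), while `NA` means the
#' question was left entirely unanswered. Ordinal and free-text answers use
#' `NA` for missing. This distinction matters for scoring: an answered-empty
#' checklist codes its item 0, an unanswered one codes it missing.
#'
#' @param respondent_id unique respondent identifier.
#' @param q1_areas character vector of ticked body-area codes,
#'   `character(0)` for none ticked, or `NA` if unanswered.
#' @param q2_pain_freq pain frequency: one of
#'   `EVERY_DAY`, `ALMOST_EVERY_DAY`, `SOME_DAYS`, or `NA`.
#' @param q3_pain_kinds character vector of pain-descriptor tokens (of 8).
#' @param q4_tired_freq tiredness frequency: `EVERY_DAY`, `SOME_DAYS`,
#'   `NEVER`, or `NA`.
#' @param q5_effort impact of physical effort on tiredness: `MUCH_MORE`,
#'   `SLIGHTLY_MORE`, `NO_DIFFERENCE`, or `NA`.
#' @param q6_symptoms character vector of symptom tokens (of 17).
#' @param q7_q12 opaque answer block for the unscored questions 7-12,
#'   preserved verbatim.
#' @param q13_recognition self-recognition in the questions asked:
#'   `ABSOLUTELY`, `A_LITTLE`, `NOT_AT_ALL`, or `NA`.
#' @param q14_text free-text health status, preserved verbatim.
#' @param label optional cohort label: `ACR_POS`, `ACR_NEG`, `FM`, `NON_FM`.
#' @return a one-row tibble; bind rows of these to build a cohort.
#' @examples
#' r <- response_record("p1",
#'   q1_areas = c("HEAD", "ARM_LEFT"), q2_pain_freq = "EVERY_DAY",
#'   q3_pain_kinds = c("BURNING", "CRAMPS", "STABBING"),
#'   q4_tired_freq = "EVERY_DAY", q5_effort = "MUCH_MORE",
#'   q6_symptoms = symptom_vocabulary()[1:7], q13_recognition = "ABSOLUTELY")
#' code_items(r)
#' @export
response_record <- function(respondent_id,
                            q1_areas = NA,
                            q2_pain_freq = NA,
                            q3_pain_kinds = NA,
                            q4_tired_freq = NA,
                            q5_effort = NA,
                            q6_symptoms = NA,
                            q7_q12 = NA,
                            q13_recognition = NA,
                            q14_text = NA,
                            label = NA) {
  tibble(
    respondent_id = as.character(respondent_id),
    label = as.character(label),
    q1_areas = list(as_multiselect(q1_areas)),
    q2_pain_freq = as.character(q2_pain_freq),
    q3_pain_kinds = list(as_multiselect(q3_pain_kinds)),
    q4_tired_freq = as.character(q4_tired_freq),
    q5_effort = as.character(q5_effort),
    q6_symptoms = list(as_multiselect(q6_symptoms)),
    q7_q12 = as.character(q7_q12),
    q13_recognition = as.character(q13_recognition),
    q14_text = as.character(q14_text)
  )
}

## canonical in-memory form of a multi-select cell:
##   character vector of tokens (possibly length 0), or NA_character_ (missing)
as_multiselect <- function(x) {
  if (is.null(x) || (length(x) == 1L && is.na(x))) return(NA_character_)
  as.character(x)
}

multi_missing <- function(x) length(x) == 1L && is.na(x[1])

cohort_columns <- function() {
  c("respondent_id", "label", "q1_areas", "q2_pain_freq", "q3_pain_kinds",
    "q4_tired_freq", "q5_effort", "q6_symptoms", "q7_q12",
    "q13_recognition", "q14_text")
}

#' Validate a cohort of questionnaire responses
#'
#' Checks structural and vocabulary invariants: required columns present,
#' respondent ids unique, multi-select tokens within their vocabularies
#' (16 body areas, 8 pain descriptors, 17 symptoms), ordinal answers at
#' their listed levels, and labels among the recognised cohort labels.
#' Validation is total: every cell is either a typed value, missing, or the
#' subject of a located error — nothing is silently coerced.
#'
#' @param cohort a cohort tibble (see [response_record()]).
#' @return the cohort, invisibly, if valid; otherwise an error naming the
#'   offending row and token/level.
#' @export
validate_responses <- function(cohort) {
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols)) {
    abort(paste0("cohort is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "fd_schema_error")
  }
  dup <- cohort$respondent_id[duplicated(cohort$respondent_id)]
  if (length(dup)) {
    abort(paste0("duplicate respondent_id: ",
                 paste(unique(dup), collapse = ", ")),
          class = "fd_integrity_error")
  }
  check_tokens(cohort, "q1_areas", body_area_taxonomy()$code)
  check_tokens(cohort, "q3_pain_kinds", pain_descriptors())
  check_tokens(cohort, "q6_symptoms", symptom_vocabulary())
  for (q in names(fd_vocab()$ordinals)) {
    bad <- which(!is.na(cohort[[q]]) & !cohort[[q]] %in% ordinal_levels(q))
    if (length(bad)) {
      abort(sprintf("row %d: invalid level '%s' for %s",
                    bad[1], cohort[[q]][bad[1]], q),
            class = "fd_validation_error")
    }
  }
  bad <- which(!is.na(cohort$label) & !cohort$label %in% cohort_labels())
  if (length(bad)) {
    abort(sprintf("row %d: unknown cohort label '%s'",
                  bad[1], cohort$label[bad[1]]),
          class = "fd_validation_error")
  }
  invisible(cohort)
}

check_tokens <- function(cohort, column, vocabulary) {
  cells <- cohort[[column]]
  for (i in seq_along(cells)) {
    x <- cells[[i]]
    if (multi_missing(x)) next
    unknown <- setdiff(x, vocabulary)
    if (length(unknown)) {
      abort(sprintf("row %d: unknown token '%s' in %s",
                    i, unknown[1], column),
            class = "fd_validation_error")
    }
  }
  invisible(TRUE)
}
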