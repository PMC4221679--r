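#' Code the nine scored items from raw questionnaire answers
#'
#' The final discriminant model keeps six questions (pain location,
#' frequency and description, tiredness frequency, effort impact, symptom
#' checklist) plus the self-recognition question, coded into nine binary
#' items:
#'
#' * `B_UPPER`, `B_ARM`, `B_LEG` — at least one silhouette area ticked in the
#'   upper-body / upper-limb / lower-limb region group;
#' * `PAIN_FREQ` — pain every day or almost every day;
#' * `PAIN_KINDS3` — at least 3 of the 8 kinds of pain ticked;
#' * `TIRED_FREQ` — tired every day;
#' * `EFFORT` — much more tired after physical effort;
#' * `SYMPT7` — at least 7 of the 17 symptoms ticked;
#' * `RECOG` — "absolutely" recognises themselves in the questions asked.
#'
#' A question answered with nothing ticked codes its item(s) 0; a question
#' left unanswered codes them `NA`. Coding never looks at the cohort label.
#'
#' @param cohort a validated cohort tibble (one row per respondent), or a
#'   single record from [response_record()].
#' @return a tibble with `respondent_id`, `label` (carried through), and the
#'   nine integer item columns (0, 1 or `NA`).
#' @seealso [compute_score()], [classify_band()], [score_responses()]
#' @export
code_items <- function(cohort) {
  upper <- region_codes("UPPER_BODY")
  arm   <- region_codes("UPPER_LIMB")
  leg   <- region_codes("LOWER_LIMB")

  region_item <- function(cells, codes) {
    vapply(cells, function(x) {
      if (multi_missing(x)) return(NA_integer_)
      as.integer(any(x %in% codes))
    }, integer(1))
  }
  count_item <- function(cells, k) {
    vapply(cells, function(x) {
      if (multi_missing(x)) return(NA_integer_)
      as.integer(length(x) >= k)
    }, integer(1))
  }
  level_item <- function(x, positive) {
    ifelse(is.na(x), NA_integer_, as.integer(x %in% positive))
  }

  tibble(
    respondent_id = cohort$respondent_id,
    label = if ("label" %in% names(cohort)) cohort$label else NA_character_,
    B_UPPER = region_item(cohort$q1_areas, upper),
    B_ARM = region_item(cohort$q1_areas, arm),
    B_LEG = region_item(cohort$q1_areas, leg),
    PAIN_FREQ = level_item(cohort$q2_pain_freq,
                           c("EVERY_DAY", "ALMOST_EVERY_DAY")),
    PAIN_KINDS3 = count_item(cohort$q3_pain_kinds, 3L),
    TIRED_FREQ = level_item(cohort$q4_tired_freq, "EVERY_DAY"),
    EFFORT = level_item(cohort$q5_effort, "MUCH_MORE"),
    SYMPT7 = count_item(cohort$q6_symptoms, 7L),
    RECOG = level_item(cohort$q13_recognition, "ABSOLUTELY")
  )
}

#' Item column names of the nine-item score
#' @return character vector of the nine item identifiers, in score order.
#' @export
item_names <- function() {
  c("B_UPPER", "B_ARM", "B_LEG", "PAIN_FREQ", "PAIN_KINDS3",
    "TIRED_FREQ", "EFFORT", "SYMPT7", "RECOG")
}

#' Compute the 0-9 screening score from coded items
#'
#' The score is the plain sum of the nine binary items and is computed only
#' for respondents with all nine items completed; any missing item sets the
#' score to missing (no imputation, no partial credit).
#'
#' @param items a tibble from [code_items()] (or any tibble containing the
#'   nine item columns).
#' @return the input with two added columns: `score` (integer 0-9 or `NA`)
#'   and `complete` (logical, all nine items answered).
#' @export
compute_score <- function(items) {
  m <- as.matrix(items[, item_names()])
  complete <- rowSums(is.na(m)) == 0L
  score <- ifelse(complete, rowSums(m), NA_integer_)
  dplyr::mutate(items, score = as.integer(score), complete = complete)
}

#' Classify a screening score into its decision band
#'
#' Scores partition into three decision bands: `LOW` (<= 3, fibromyalgia
#' unlikely, no referral), `MID` (4-5, indeterminate, further evaluation),
#' and `HIGH` (>= 6, likely, refer to a specialist). Missing scores are
#' refused rather than defaulted — callers must exclude them first, matching
#' the convention that missing data enter no percentage.
#'
#' @param score integer vector of scores in 0..9 (no `NA`).
#' @return factor with levels `LOW`, `MID`, `HIGH`.
#' @export
classify_band <- function(score) {
  if (anyNA(score)) {
    abort("classify_band() requires non-missing scores; filter them first",
          class = "fd_contract_error")
  }
  if (any(score < 0 | score > 9)) {
    abort("scores must lie in 0..9", class = "fd_contract_error")
  }
  cut(score, breaks = c(-Inf, 3, 5, Inf), labels = c("LOW", "MID", "HIGH"))
}

#' Score a raw cohort end to end
#'
#' Convenience pipeline: validate, code items, sum the score, and attach the
#' decision band (`NA` band for missing scores).
#'
#' @param cohort a cohort tibble of raw responses.
#' @return tibble with id, label, the nine items, `score`, `complete`, `band`.
#' @examples
#' cfg <- group_config("FM", n = 5, seed = 1)
#' generate_cohort(cfg) |> score_responses()
#' @export
score_responses <- function(cohort) {
  validate_responses(cohort)
  scored <- compute_score(code_items(cohort))
  band <- factor(rep(NA_character_, nrow(scored)),
                 levels = c("LOW", "MID", "HIGH"))
  ok <- !is.na(scored$score)
  band[ok] <- classify_band(scored$score[ok])
  dplyr::mutate(scored, band = band)
}
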