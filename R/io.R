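#' Read and write cohort CSV files
#'
#' Cohorts are stored as plain CSV with one row per respondent and the fixed
#' column dictionary `respondent_id, label, q1_areas, q2_pain_freq,
#' q3_pain_kinds, q4_tired_freq, q5_effort, q6_symptoms, q7_q12,
#' q13_recognition, q14_text`. Multi-select cells are semicolon-delimited
#' uppercase tokens; an empty cell means the question was left unanswered
#' (missing), and the sentinel `NONE` records a question that was answered
#' with nothing ticked. `read_responses(write_responses(x))` reproduces `x`
#' field for field.
#'
#' @param path file path of the cohort CSV.
#' @param delim token delimiter inside multi-select cells (default `";"`).
#' @return `read_responses()` returns a validated cohort tibble;
#'   `write_responses()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_responses(response_record("p1", q2_pain_freq = "EVERY_DAY"), f)
#' read_responses(f)
#' @export
read_responses <- function(path, delim = ";") {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "fd_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), na = character(), progress = FALSE)
  unknown <- setdiff(names(raw), cohort_columns())
  if (length(unknown)) {
    abort(paste0("unknown column(s) in ", path, ": ",
                 paste(unknown, collapse = ", ")),
          class = "fd_schema_error")
  }
  missing_cols <- setdiff(cohort_columns(), names(raw))
  if (length(missing_cols)) {
    abort(paste0("missing column(s) in ", path, ": ",
                 paste(missing_cols, collapse = ", ")),
          class = "fd_schema_error")
  }
  cohort <- tibble(
    respondent_id = raw$respondent_id,
    label = scalar_in(raw$label),
    q1_areas = parse_multiselect(raw$q1_areas, delim),
    q2_pain_freq = scalar_in(raw$q2_pain_freq),
    q3_pain_kinds = parse_multiselect(raw$q3_pain_kinds, delim),
    q4_tired_freq = scalar_in(raw$q4_tired_freq),
    q5_effort = scalar_in(raw$q5_effort),
    q6_symptoms = parse_multiselect(raw$q6_symptoms, delim),
    q7_q12 = scalar_in(raw$q7_q12),
    q13_recognition = scalar_in(raw$q13_recognition),
    q14_text = scalar_in(raw$q14_text)
  )
  validate_responses(cohort)
  cohort
}

#' @rdname read_responses
#' @param cohort a valid cohort tibble.
#' @export
write_responses <- function(cohort, path, delim = ";") {
  validate_responses(cohort)
  out <- tibble(
    respondent_id = cohort$respondent_id,
    label = scalar_out(cohort$label),
    q1_areas = format_multiselect(cohort$q1_areas, delim),
    q2_pain_freq = scalar_out(cohort$q2_pain_freq),
    q3_pain_kinds = format_multiselect(cohort$q3_pain_kinds, delim),
    q4_tired_freq = scalar_out(cohort$q4_tired_freq),
    q5_effort = scalar_out(cohort$q5_effort),
    q6_symptoms = format_multiselect(cohort$q6_symptoms, delim),
    q7_q12 = scalar_out(cohort$q7_q12),
    q13_recognition = scalar_out(cohort$q13_recognition),
    q14_text = scalar_out(cohort$q14_text)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

## "" <-> NA for scalar columns
scalar_in <- function(x) ifelse(x == "", NA_character_, x)
scalar_out <- function(x) ifelse(is.na(x), "", x)

## "" = missing, "NONE" = answered-empty, otherwise delimited tokens
parse_multiselect <- function(x, delim) {
  lapply(x, function(cell) {
    if (cell == "") return(NA_character_)
    if (cell == "NONE") return(character(0))
    strsplit(cell, delim, fixed = TRUE)[[1]]
  })
}

format_multiselect <- function(cells, delim) {
  vapply(cells, function(x) {
    if (multi_missing(x)) return("")
    if (length(x) == 0L) return("NONE")
    paste(x, collapse = delim)
  }, character(1))
}
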