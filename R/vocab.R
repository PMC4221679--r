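#' Questionnaire vocabulary: body areas, pain descriptors, symptoms
#'
#' The screening leaflet presents a front/back body silhouette divided into
#' 16 areas, a checklist of 8 kinds of pain, and a checklist of 17 associated
#' symptoms. The canonical token vocabulary ships with the package as a
#' versioned YAML file (`inst/extdata/vocabulary.yaml`); these accessors load
#' it once per session.
#'
#' Scoring only consumes the silhouette through three region groups —
#' `UPPER_BODY` (head, neck, shoulders), `UPPER_LIMB` (arms/hands) and
#' `LOWER_LIMB` (legs/feet). Trunk areas are tagged `TRUNK_OTHER` and feed no
#' coded item.
#'
#' @return `body_area_taxonomy()` returns a tibble with columns `code` and
#'   `region` (16 rows). `pain_descriptors()` and `symptom_vocabulary()`
#'   return character vectors of the valid tokens. `cohort_labels()` returns
#'   the four recognised group labels. `ordinal_levels(question)` returns the
#'   ordered response levels of an ordinal question.
#' @examples
#' body_area_taxonomy()
#' ordinal_levels("q2_pain_freq")
#' @export
body_area_taxonomy <- function() {
  fd_vocab()$areas
}

fd_vocab <- function() {
  if (is.null(.fd_env$vocab)) {
    path <- system.file("extdata", "vocabulary.yaml", package = "fibrodetect",
                        mustWork = TRUE)
    raw <- yaml::read_yaml(path)
    areas <- dplyr::bind_rows(lapply(raw$body_areas, as_tibble))
    stopifnot(nrow(areas) == 16L, !anyDuplicated(areas$code))
    .fd_env$vocab <- list(
      version = raw$version,
      areas = areas,
      pain = as.character(raw$pain_descriptors),
      symptoms = as.character(raw$symptoms),
      ordinals = lapply(raw$ordinals, as.character),
      labels = as.character(raw$labels)
    )
  }
  .fd_env$vocab
}

#' @rdname body_area_taxonomy
#' @export
pain_descriptors <- function() fd_vocab()$pain

#' @rdname body_area_taxonomy
#' @export
symptom_vocabulary <- function() fd_vocab()$symptoms

#' @rdname body_area_taxonomy
#' @export
cohort_labels <- function() fd_vocab()$labels

#' @rdname body_area_taxonomy
#' @param question name of an ordinal question column, e.g. `"q2_pain_freq"`.
#' @export
ordinal_levels <- function(question) {
  levels <- fd_vocab()$ordinals[[question]]
  if (is.null(levels)) {
    abort(paste0("unknown ordinal question: ", question))
  }
  levels
}

## region membership lookup used by the item coder
region_codes <- function(region) {
  tax <- body_area_taxonomy()
  tax$code[tax$region == region]
}
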