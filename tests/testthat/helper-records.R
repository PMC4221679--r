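# Record builders used across the suite.

## complete response triggering every coding rule -> score 9
max_record <- function(id = "max") {
  response_record(
    id,
    q1_areas = c("HEAD", "ARM_RIGHT", "LEG_LEFT"),
    q2_pain_freq = "EVERY_DAY",
    q3_pain_kinds = c("BURNING", "CRAMPS", "STABBING"),
    q4_tired_freq = "EVERY_DAY",
    q5_effort = "MUCH_MORE",
    q6_symptoms = symptom_vocabulary()[1:7],
    q13_recognition = "ABSOLUTELY"
  )
}

## complete response triggering no coding rule -> score 0
min_record <- function(id = "min") {
  response_record(
    id,
    q1_areas = character(0),
    q2_pain_freq = "SOME_DAYS",
    q3_pain_kinds = character(0),
    q4_tired_freq = "NEVER",
    q5_effort = "NO_DIFFERENCE",
    q6_symptoms = character(0),
    q13_recognition = "NOT_AT_ALL"
  )
}

## small two-group synthetic cohort for pipeline tests
two_group_cohort <- function(n = 60, seed = 1, mu_pos = 1.2, mu_neg = -0.6) {
  dplyr::bind_rows(
    generate_cohort(group_config("ACR_POS", n = n, mu = mu_pos,
                                 seed = seed)),
    generate_cohort(group_config("ACR_NEG", n = n, mu = mu_neg,
                                 seed = seed + 1000))
  )
}
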