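test_that("a fully endorsed response codes all nine items 1 and scores 9", {
  scored <- compute_score(code_items(max_record()))
  expect_equal(unname(unlist(scored[item_names()])), rep(1L, 9))
  expect_equal(scored$score, 9L)
  expect_true(scored$complete)
})

test_that("a fully non-endorsed complete response scores 0", {
  scored <- compute_score(code_items(min_record()))
  expect_equal(unname(unlist(scored[item_names()])), rep(0L, 9))
  expect_equal(scored$score, 0L)
})

test_that("item coding follows the published cut rules at their boundaries", {
  # pain kinds: 2 ticked -> 0, 3 -> 1
  r2 <- code_items(response_record("a", q3_pain_kinds = pain_descriptors()[1:2]))
  r3 <- code_items(response_record("b", q3_pain_kinds = pain_descriptors()[1:3]))
  expect_equal(r2$PAIN_KINDS3, 0L)
  expect_equal(r3$PAIN_KINDS3, 1L)
  # symptoms: 6 -> 0, 7 -> 1
  s6 <- code_items(response_record("c", q6_symptoms = symptom_vocabulary()[1:6]))
  s7 <- code_items(response_record("d", q6_symptoms = symptom_vocabulary()[1:7]))
  expect_equal(s6$SYMPT7, 0L)
  expect_equal(s7$SYMPT7, 1L)
  # pain frequency: both near-daily levels code 1, some days codes 0
  expect_equal(code_items(response_record("e",
    q2_pain_freq = "ALMOST_EVERY_DAY"))$PAIN_FREQ, 1L)
  expect_equal(code_items(response_record("f",
    q2_pain_freq = "SOME_DAYS"))$PAIN_FREQ, 0L)
  # tiredness: only every day codes 1
  expect_equal(code_items(response_record("g",
    q4_tired_freq = "SOME_DAYS"))$TIRED_FREQ, 0L)
  # effort / recognition: only the top level codes 1
  expect_equal(code_items(response_record("h",
    q5_effort = "SLIGHTLY_MORE"))$EFFORT, 0L)
  expect_equal(code_items(response_record("i",
    q13_recognition = "A_LITTLE"))$RECOG, 0L)
})

test_that("region items reflect region-group membership of ticked areas", {
  r <- code_items(response_record("a",
    q1_areas = c("NECK", "FOOT_RIGHT", "CHEST")))
  expect_equal(r$B_UPPER, 1L)
  expect_equal(r$B_ARM, 0L)
  expect_equal(r$B_LEG, 1L)
  # answered-empty silhouette codes 0, not missing
  r0 <- code_items(response_record("b", q1_areas = character(0)))
  expect_equal(c(r0$B_UPPER, r0$B_ARM, r0$B_LEG), c(0L, 0L, 0L))
  # trunk-only silhouette codes no region item
  rt <- code_items(response_record("c", q1_areas = c("CHEST", "LOWER_BACK")))
  expect_equal(c(rt$B_UPPER, rt$B_ARM, rt$B_LEG), c(0L, 0L, 0L))
  # unanswered silhouette codes all three missing
  rna <- code_items(response_record("d"))
  expect_true(all(is.na(c(rna$B_UPPER, rna$B_ARM, rna$B_LEG))))
})

test_that("the score is missing unless all nine items are completed", {
  r <- max_record()
  r$q13_recognition <- NA_character_
  scored <- compute_score(code_items(r))
  expect_true(is.na(scored$score))
  expect_false(scored$complete)
  # and the score equals a brute-force count of endorsed items when complete
  cohort <- generate_cohort(group_config("ACR_NEG", n = 200, seed = 8))
  scored <- compute_score(code_items(cohort))
  complete <- scored[scored$complete, ]
  brute <- apply(as.matrix(complete[item_names()]), 1,
                 function(v) sum(v == 1))
  expect_equal(complete$score, as.integer(brute))
  expect_true(all(complete$score >= 0 & complete$score <= 9))
})

test_that("band classification partitions 0-9 and refuses missing", {
  expect_equal(as.character(classify_band(c(0, 3, 4, 5, 6, 9))),
               c("LOW", "LOW", "MID", "MID", "HIGH", "HIGH"))
  expect_error(classify_band(c(2, NA)), class = "fd_contract_error")
  expect_error(classify_band(10), class = "fd_contract_error")
})

test_that("adding ticks never decreases items, score or band (monotonicity)", {
  set.seed(42)
  for (i in 1:25) {
    cohort <- generate_cohort(group_config("NON_FM", n = 1, mu = rnorm(1),
                                           seed = 100 + i,
                                           miss_rates = setNames(rep(0, 7),
                                             c("q1","q2","q3","q4","q5","q6","q13"))))
    base <- compute_score(code_items(cohort))
    grown <- cohort
    grown$q1_areas[[1]] <- union(grown$q1_areas[[1]], "HEAD")
    grown$q3_pain_kinds[[1]] <- union(grown$q3_pain_kinds[[1]],
      setdiff(pain_descriptors(), grown$q3_pain_kinds[[1]])[1])
    grown$q6_symptoms[[1]] <- union(grown$q6_symptoms[[1]],
      setdiff(symptom_vocabulary(), grown$q6_symptoms[[1]])[1])
    more <- compute_score(code_items(grown))
    expect_true(all(unlist(more[item_names()]) >= unlist(base[item_names()])))
    expect_gte(more$score, base$score)
  }
})

test_that("coding is deterministic and blind to the cohort label", {
  cohort <- generate_cohort(group_config("FM", n = 30, seed = 4))
  relabelled <- dplyr::mutate(cohort, label = "NON_FM")
  a <- code_items(cohort)[item_names()]
  b <- code_items(relabelled)[item_names()]
  expect_identical(a, b)
})
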