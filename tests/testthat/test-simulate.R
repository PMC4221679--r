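no_missing <- function() {
  setNames(rep(0, 7), c("q1", "q2", "q3", "q4", "q5", "q6", "q13"))
}

test_that("the same configuration and seed reproduce a byte-identical cohort", {
  cfg <- group_config("FM", n = 40, mu = 0.7, seed = 31)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_responses(a, f1); write_responses(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("appending respondents never perturbs earlier ones", {
  cfg_small <- group_config("ACR_NEG", n = 30, seed = 32)
  cfg_big <- group_config("ACR_NEG", n = 45, seed = 32)
  small <- generate_cohort(cfg_small)
  big <- generate_cohort(cfg_big)
  expect_identical(as.data.frame(small), as.data.frame(big[1:30, ]))
})

test_that("degenerate offsets force the score to its bounds", {
  always <- group_config("FM", n = 15, seed = 33,
                         item_offsets = setNames(rep(-10, 9), item_names()),
                         miss_rates = no_missing())
  never <- group_config("FM", n = 15, seed = 33,
                        item_offsets = setNames(rep(10, 9), item_names()),
                        miss_rates = no_missing())
  expect_true(all(score_responses(generate_cohort(always))$score == 9))
  expect_true(all(score_responses(generate_cohort(never))$score == 0))
})

test_that("generated cohorts validate and respect their vocabularies", {
  cohort <- generate_cohort(group_config("NON_FM", n = 80, mu = -0.3,
                                         seed = 34))
  expect_silent(validate_responses(cohort))
  expect_true(all(unlist(purrr::map(cohort$q3_pain_kinds, length)) <= 8))
  expect_true(all(unlist(purrr::map(cohort$q6_symptoms, length)) <= 17))
})

test_that("the mean score is monotone in the latent separation mu", {
  means <- purrr::map_dbl(c(-1, 0, 1, 2), function(m) {
    sc <- score_responses(generate_cohort(
      group_config("FM", n = 4000, mu = m, seed = 35,
                   miss_rates = no_missing())))
    mean(sc$score)
  })
  expect_true(all(diff(means) > 0))
})

test_that("with rho = 0 the coded items are uncorrelated within 3 SE", {
  cohort <- generate_cohort(group_config("ACR_POS", n = 4000, rho = 0,
                                         seed = 36,
                                         miss_rates = no_missing()))
  items <- as.matrix(code_items(cohort)[item_names()])
  cors <- cor(items)
  off_diag <- cors[upper.tri(cors)]
  # family-wise bound for the 36 simultaneous null correlations (~1% level)
  crit <- qnorm(1 - 0.005 / length(off_diag)) / sqrt(nrow(items))
  expect_true(all(abs(off_diag) < crit))
})

test_that("the missing-score fraction matches the per-question MCAR rates", {
  rates <- setNames(rep(0.05, 7), c("q1", "q2", "q3", "q4", "q5", "q6", "q13"))
  cohort <- generate_cohort(group_config("FM", n = 6000, seed = 37,
                                         miss_rates = rates))
  sc <- score_responses(cohort)
  expected <- 1 - prod(1 - rates)
  observed <- mean(is.na(sc$score))
  se <- sqrt(expected * (1 - expected) / nrow(cohort))
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("invalid configurations are rejected before simulation", {
  expect_error(group_config("FM", n = 0, seed = 1),
               class = "fd_config_error")
  expect_error(group_config("FM", n = 5, rho = 1, seed = 1),
               class = "fd_config_error")
  expect_error(group_config("BADLABEL", n = 5, seed = 1),
               class = "fd_config_error")
  bad_rates <- setNames(rep(0.5, 7), c("q1","q2","q3","q4","q5","q6","q13"))
  expect_error(group_config("FM", n = 5, miss_rates = bad_rates, seed = 1),
               class = "fd_config_error")
})

test_that("group configurations round-trip through YAML", {
  cfg <- group_config("ACR_POS", n = 12, mu = 0.4, rho = 0.3, seed = 38)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_group_config(cfg, f)
  back <- read_group_config(f)
  expect_equal(back, cfg)
  expect_identical(generate_cohort(back), generate_cohort(cfg))
})

test_that("shipped group configurations load and carry the study group sizes", {
  sizes <- c(acr_pos = 137L, acr_neg = 139L, fm = 158L, non_fm = 154L)
  for (g in names(sizes)) {
    cfg <- shipped_group_config(g)
    expect_s3_class(cfg, "fd_group_config")
    expect_equal(cfg$n, sizes[[g]])
  }
})
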