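# score multisets reconstructed from published per-group band counts;
# concrete values within a band are arbitrary (band membership is all that
# the band table and cutoff arithmetic consume)
band_scores <- function(n_low, n_mid, n_high, n_missing = 0) {
  c(rep(2L, n_low), rep(4L, n_mid), rep(7L, n_high),
    rep(NA_integer_, n_missing))
}

test_that("band table reproduces the published validation-group percentages", {
  scored <- tibble::tibble(
    label = c(rep("FM", 158), rep("NON_FM", 154)),
    score = c(band_scores(4, 12, 137, 5), band_scores(47, 52, 49, 6))
  )
  bt <- band_table(scored)
  fm <- bt[bt$group == "FM", ]
  expect_equal(fm$n, 153)
  expect_equal(fm$pct_high, 100 * 137 / 153)  # prints as 89.5
  expect_equal(round(fm$pct_high, 1), 89.5)
  nf <- bt[bt$group == "NON_FM", ]
  expect_equal(nf$n, 148)
  expect_equal(round(nf$pct_low, 1), 31.8)
  expect_equal(round(nf$pct_mid, 1), 35.1)
  expect_equal(round(nf$pct_high, 1), 33.1)
})

test_that("cutoff performance reproduces the published operating points", {
  acr_pos <- band_scores(11, 19, 99)
  acr_neg <- band_scores(28, 53, 52)
  dev <- cutoff_performance(acr_pos, acr_neg, cutoff = 6)
  expect_equal(round(100 * dev$sensitivity), 77)  # 99/129
  expect_equal(round(100 * dev$specificity), 61)  # 81/133
  fm <- band_scores(4, 12, 137)
  non_fm <- band_scores(47, 52, 49)
  ctl <- cutoff_performance(fm, non_fm, cutoff = 6)
  expect_equal(round(100 * ctl$specificity), 67)  # 99/148
  expect_equal(round(100 * ctl$sensitivity, 1), 89.5)
})

test_that("evaluate_scores separates a perfectly separated cohort with AUC 1", {
  scored <- tibble::tibble(
    label = rep(c("FM", "NON_FM"), each = 10),
    score = c(rep(9L, 10), rep(0L, 10))
  )
  ev <- evaluate_scores(scored, "FM", "NON_FM")
  expect_equal(ev$auc, 1)
  expect_true(ev$selected$feasible)
  expect_equal(ev$selected$sensitivity, 1)
  expect_equal(ev$selected$specificity, 1)
  expect_equal(nrow(ev$bands), 2)
})

test_that("missing scores are excluded and empty classes rejected", {
  scored <- tibble::tibble(
    label = rep(c("FM", "NON_FM"), each = 4),
    score = c(7L, 8L, NA, NA, 1L, 2L, NA, 3L)
  )
  ev <- evaluate_scores(scored, "FM", "NON_FM")
  expect_equal(ev$roc$n_pos, 2)
  expect_equal(ev$roc$n_neg, 3)
  all_na <- tibble::tibble(label = c("FM", "NON_FM"),
                           score = c(NA_integer_, 3L))
  expect_error(evaluate_scores(all_na, "FM", "NON_FM"),
               class = "fd_contract_error")
})

test_that("the full pipeline validates a well-separated synthetic contrast", {
  cohort <- dplyr::bind_rows(
    generate_cohort(group_config("FM", n = 120, mu = 1.8, seed = 51)),
    generate_cohort(group_config("NON_FM", n = 120, mu = -0.5, seed = 52))
  )
  ev <- validate_cohort(cohort, "FM", "NON_FM")
  expect_gt(ev$auc, 0.8)
  expect_equal(ev$thresholds$threshold, 0:10)
})
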