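test_that("ROC handles the canonical separation cases", {
  expect_equal(roc_curve(c(7, 8, 9), c(1, 2, 3))$auc, 1)
  expect_equal(roc_curve(c(2, 5, 7), c(2, 5, 7))$auc, 0.5)
  # 4 pairs: win, win, loss, tie/2 -> 2.5/4
  expect_equal(roc_curve(c(2, 3), c(1, 3))$auc, 0.625)
  expect_error(roc_curve(numeric(0), c(1)), class = "fd_contract_error")
})

test_that("sensitivity decreases and specificity increases in the threshold", {
  set.seed(11)
  pts <- roc_curve(sample(0:9, 30, TRUE), sample(0:9, 30, TRUE))$points
  expect_true(all(diff(pts$sensitivity) <= 0))
  expect_true(all(diff(pts$specificity) >= 0))
  expect_equal(pts$threshold, 0:10)
})

test_that("trapezoidal AUC equals Mann-Whitney concordance on random cohorts", {
  set.seed(12)
  for (i in 1:200) {
    pos <- sample(0:9, sample(2:20, 1), replace = TRUE)
    neg <- sample(0:9, sample(2:20, 1), replace = TRUE)
    expect_equal(roc_curve(pos, neg)$auc, concordance_auc(pos, neg))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  for (i in 1:20) {
    pos <- sample(0:9, 25, replace = TRUE)
    neg <- sample(0:9, 25, replace = TRUE)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = rep(c(1, 0), each = 25), predictor = c(pos, neg),
      quiet = TRUE, direction = "<")))
    expect_equal(roc_curve(pos, neg)$auc, ref)
  }
})

test_that("AUC is invariant to monotone transformation of the scores", {
  set.seed(14)
  pos <- sample(0:9, 15, TRUE); neg <- sample(0:9, 15, TRUE)
  base <- roc_curve(pos, neg)$auc
  expect_equal(roc_curve(2 * pos + 1, 2 * neg + 1)$auc, base)
  expect_equal(roc_curve(exp(pos / 3), exp(neg / 3))$auc, base)
})

test_that("shifting every positive score up by 1 never decreases AUC", {
  set.seed(15)
  for (i in 1:50) {
    pos <- sample(0:8, 12, TRUE); neg <- sample(0:9, 12, TRUE)
    expect_gte(roc_curve(pos + 1, neg)$auc, roc_curve(pos, neg)$auc)
  }
})

test_that("threshold selection applies the sensitivity/specificity rule", {
  mk_curve <- function(pts) {
    structure(list(points = pts, auc = NA_real_, n_pos = 1, n_neg = 1),
              class = "fd_roc")
  }
  pts <- tibble::tibble(threshold = 4:6,
                        sensitivity = c(0.97, 0.95, 0.80),
                        specificity = c(0.40, 0.55, 0.70))
  sel <- select_threshold(mk_curve(pts))
  expect_equal(sel$threshold, 5)
  expect_true(sel$feasible)
  # perfectly separated cohorts: separating threshold with sens = spec = 1
  sep <- select_threshold(roc_curve(c(7, 8, 9), c(1, 2, 3)))
  expect_true(sep$feasible)
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
  # specificity floor unreachable at target sensitivity -> flagged result
  pts2 <- tibble::tibble(threshold = 0:2,
                         sensitivity = c(1, 0.96, 0.90),
                         specificity = c(0, 0.30, 0.80))
  sel2 <- select_threshold(mk_curve(pts2))
  expect_false(sel2$feasible)
  expect_equal(sel2$threshold, 1)
})
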