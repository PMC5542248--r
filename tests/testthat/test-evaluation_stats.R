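test_that("confusion metrics follow their defining formulas", {
  r <- confusion_and_metrics(c("c", "c", "n", "n"), c("c", "c", "n", "n"))
  expect_equal(unname(r$confusion), c(2L, 0L, 2L, 0L))
  expect_equal(c(r$sensitivity, r$specificity, r$ppv, r$npv), rep(1, 4))

  # no positive predictions: ppv undefined, never 0
  r2 <- confusion_and_metrics(c("c", "n"), c("n", "n"))
  expect_equal(r2$sensitivity, 0)
  expect_equal(r2$npv, 0.5)
  expect_true(is.na(r2$ppv))

  expect_error(confusion_and_metrics("c", c("c", "n")), "equal length")
  expect_error(confusion_and_metrics("x", "c"), "labels")
})

test_that("metrics match brute-force counting on random label pairs", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    truth <- sample(c("c", "n"), n, replace = TRUE)
    pred <- sample(c("c", "n"), n, replace = TRUE)
    r <- confusion_and_metrics(truth, pred)
    tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
    for (j in seq_len(n)) {  # independent element-wise tally
      if (truth[j] == "c" && pred[j] == "c") tp <- tp + 1L
      if (truth[j] == "n" && pred[j] == "c") fp <- fp + 1L
      if (truth[j] == "n" && pred[j] == "n") tn <- tn + 1L
      if (truth[j] == "c" && pred[j] == "n") fn <- fn + 1L
    }
    expect_equal(unname(r$confusion), c(tp, fp, tn, fn))
    if (tp + fn > 0) expect_equal(r$sensitivity, tp / (tp + fn))
    if (tn + fp > 0) expect_equal(r$specificity, tn / (tn + fp))
  }
})

test_that("swapping the positive class swaps the paired metrics", {
  set.seed(56)
  truth <- sample(c("c", "n"), 60, replace = TRUE, prob = c(0.4, 0.6))
  pred <- sample(c("c", "n"), 60, replace = TRUE)
  flip <- function(z) ifelse(z == "c", "n", "c")
  r <- confusion_and_metrics(truth, pred)
  rf <- confusion_and_metrics(flip(truth), flip(pred))
  expect_equal(r$sensitivity, rf$specificity)
  expect_equal(r$specificity, rf$sensitivity)
  expect_equal(r$ppv, rf$npv)
  expect_equal(r$npv, rf$ppv)
})

test_that("rank AUC matches the all-pairs oracle and pROC", {
  expect_equal(auc_rank(c(3, 4, 1, 2), c("c", "c", "n", "n")), 1)
  expect_equal(auc_rank(rep(1, 6), rep(c("c", "n"), 3)), 0.5)
  set.seed(91)
  scores <- round(rnorm(50), 1)  # rounding forces ties
  truth <- sample(c("c", "n"), 50, replace = TRUE)
  a <- auc_rank(scores, truth)
  sc <- scores[truth == "c"]; sn <- scores[truth == "n"]
  pairs <- outer(sc, sn, function(u, v) (u > v) + 0.5 * (u == v))
  expect_equal(a, mean(pairs))
  skip_if_not_installed("pROC")
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = scores, levels = c("n", "c"),
    direction = "<", quiet = TRUE))))
  expect_error(auc_rank(1:3, c("c", "c", "c")), "single class")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(92)
  scores <- rnorm(40)
  truth <- sample(c("c", "n"), 40, replace = TRUE)
  a <- auc_rank(scores, truth)
  expect_equal(auc_rank(exp(scores), truth), a)
  expect_equal(auc_rank(scores^3 + 5 * scores, truth), a)
})

test_that("the Yates chi-square reproduces the follow-up comparison", {
  tab <- matrix(c(4, 3, 7, 54), 2,
                dimnames = list(c("high", "low"),
                                c("transformed", "not_transformed")))
  res <- yates_chi_square(tab)
  expect_equal(round(res$p_value, 2), 0.01)
  expect_equal(res$df, 1L)
  # perfectly independent table: clamped correction gives exactly 0
  flat <- yates_chi_square(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(yates_chi_square(matrix(c(0, 0, 3, 4), 2)), "degenerate")
})

test_that("Yates statistic matches chisq.test and never exceeds Pearson", {
  set.seed(71)
  for (i in 1:100) {
    m <- matrix(rpois(4, 8) + 1L, 2)
    res <- yates_chi_square(m)
    ref <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
    pearson <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_lte(res$statistic, unname(pearson$statistic) + 1e-12)
    expect_gte(res$statistic, 0)
    expect_gt(res$p_value, 0)
    expect_lte(res$p_value, 1)
  }
})

test_that("proportion summaries reproduce the printed percentages", {
  tab <- matrix(c(4, 3, 7, 54), 2,
                dimnames = list(c("high", "low"),
                                c("transformed", "not_transformed")))
  s <- proportion_summary(tab)
  expect_equal(s$percent, c(36.4, 5.3))
  expect_equal(s$fraction, c(4 / 11, 3 / 57))
  expect_equal(proportion_summary(matrix(c(0, 1, 5, 4), 2))$percent[1], 0)
  expect_error(proportion_summary(matrix(c(0, 1, 0, 4), 2)), "no cases")
})

test_that("the 2x3 comparison uses uncorrected Pearson chi-square", {
  # identical outcome proportions across categories: statistic 0
  even <- matrix(c(2, 4, 3, 6, 5, 10), 2)
  res <- multi_group_chi_square(even)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 2L)

  set.seed(72)
  m <- matrix(rpois(6, 6) + 1L, 2)
  ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  got <- multi_group_chi_square(m)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)

  # an empty third category leaves the statistic and df unchanged
  m23 <- cbind(m, c(0, 0))
  got23 <- multi_group_chi_square(m23)
  expect_equal(got23$statistic, got$statistic)
  expect_equal(got23$df, got$df)
  expect_error(multi_group_chi_square(matrix(c(1, 0, 0, 0, 2, 0), 2)),
               "degenerate")
})

test_that("followup_table tallies per-case outcomes", {
  risk <- c("high", "high", "low", "low", "low")
  tr <- c(TRUE, FALSE, FALSE, TRUE, FALSE)
  m <- followup_table(risk, tr)
  expect_equal(unname(m["high", ]), c(1L, 1L))
  expect_equal(unname(m["low", ]), c(1L, 2L))
})
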