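test_that("the optimisation/holdout split is stratified and deterministic", {
  tab <- separable_table(100L)  # 100 c + 100 n
  sp <- split_optimization_holdout(tab, 0.7, seed = 3)
  expect_equal(sum(sp$optimization$label == "c"), 70L)
  expect_equal(sum(sp$optimization$label == "n"), 70L)
  expect_equal(nrow(sp$optimization) + nrow(sp$holdout), 200L)
  expect_length(intersect(sp$optimization$case_id, sp$holdout$case_id), 0L)

  sp2 <- split_optimization_holdout(tab, 0.7, seed = 3)
  expect_identical(sp, sp2)
  sp3 <- split_optimization_holdout(tab, 0.7, seed = 4)
  expect_false(identical(sp$optimization$case_id, sp3$optimization$case_id))

  # the SVMfull case: fraction 1 leaves nothing held out
  full <- split_optimization_holdout(tab, 1, seed = 1)
  expect_equal(nrow(full$optimization), 200L)
  expect_equal(nrow(full$holdout), 0L)

  thin <- feature_table(matrix(0L, 3, 10), c("c", "n", "n"), c("a", "b", "d"))
  expect_error(split_optimization_holdout(thin, 0.7, 1), ">= 2 rows")
})

test_that("tuning records one row per candidate and picks the best", {
  tab <- separable_table(20L)
  spec <- model_spec("rf", cv_folds = 5L, cv_repeats = 2L, seed = 7)
  model <- tune_and_train(tab, spec)
  expect_equal(nrow(model$tuning), 3L)  # mtry grid {2, 6, 10}
  expect_named(model$tuning, c("mtry", "mean_cv_accuracy"))
  expect_true(all(model$tuning$mean_cv_accuracy >= 0 &
                    model$tuning$mean_cv_accuracy <= 1))
  best <- which.max(model$tuning$mean_cv_accuracy)
  expect_equal(model$params$mtry, model$tuning$mtry[best])
  expect_equal(model$class_counts, c(c = 20L, n = 20L))
})

test_that("a separable table is classified perfectly on holdout", {
  tab <- separable_table(30L)
  sp <- split_optimization_holdout(tab, 0.7, seed = 11)
  spec <- model_spec("rf", cv_folds = 5L, cv_repeats = 2L, seed = 11)
  model <- tune_and_train(sp$optimization, spec)
  p <- compute_ocri2(model, sp$holdout)
  pred <- ifelse(p >= 0.5, "c", "n")
  expect_equal(unname(pred), sp$holdout$label)
})

test_that("training rejects invalid inputs with clear messages", {
  tab <- separable_table(10L)
  with_k <- feature_table(rbind(as.matrix(as.data.frame(tab)[, 1:10]),
                                matrix(0L, 1, 10)),
                          c(tab$label, "k"), c(tab$case_id, "K1"))
  spec <- model_spec("rf", cv_folds = 5L, seed = 1)
  expect_error(tune_and_train(with_k, spec), "'c' and 'n'")

  only_n <- feature_table(matrix(0L, 4, 10), rep("n", 4), letters[1:4])
  expect_error(tune_and_train(only_n, spec), "both classes")

  expect_error(tune_and_train(separable_table(4L),
                              model_spec("rf", cv_folds = 10L, seed = 1)),
               "cv_folds")
})

test_that("seeded training is exactly reproducible", {
  tab <- separable_table(15L)
  spec <- model_spec("rf", cv_folds = 5L, cv_repeats = 2L, seed = 42)
  m1 <- tune_and_train(tab, spec)
  m2 <- tune_and_train(tab, spec)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$tuning, m2$tuning)
  probe <- separable_table(8L, prefix = "q")
  expect_identical(compute_ocri2(m1, probe), compute_ocri2(m2, probe))
})

test_that("rf OCRI2 equals the per-tree vote fraction", {
  tab <- separable_table(15L)
  spec <- model_spec("rf", cv_folds = 5L, cv_repeats = 1L, seed = 9)
  model <- tune_and_train(tab, spec)
  probe <- separable_table(10L, prefix = "p")  # 20 rows
  p <- compute_ocri2(model, probe)
  x <- as.matrix(as.data.frame(probe)[, 1:10])
  per_tree <- predict(model$fit, newdata = x, predict.all = TRUE)$individual
  vote_c <- rowMeans(per_tree == "c")
  expect_equal(unname(p), unname(vote_c))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("every model kind yields OCRI2 probabilities in [0, 1]", {
  tab <- separable_table(12L)
  set.seed(64)
  probe_counts <- matrix(rpois(200, 1), 20L, 10L)
  probe <- feature_table(probe_counts, rep("u", 20), sprintf("r%02d", 1:20))
  for (kind in c("rf", "svm", "svmfull", "knn", "cf")) {
    spec <- model_spec(kind, cv_folds = 4L, cv_repeats = 1L, seed = 2)
    model <- tune_and_train(tab, spec)
    p <- compute_ocri2(model, probe)
    expect_length(p, 20L)
    expect_true(all(p >= 0 & p <= 1), info = kind)
  }
})

test_that("risk stratification uses the inclusive 0.5 boundary", {
  expect_equal(stratify_risk(0.5), "high")
  expect_equal(stratify_risk(0.49), "low")
  expect_equal(stratify_risk(0), "low")
  expect_equal(stratify_risk(1), "high")
  expect_equal(stratify_risk(c(0.2, 0.8)), c("low", "high"))
  expect_error(stratify_risk(1.2), "\\[0, 1\\]")
  expect_error(stratify_risk(-0.1), "\\[0, 1\\]")
})

test_that("cross-examination separates planted cohorts in both directions", {
  pair <- synthetic_cohort_pair(25L, seed_a = 301L, seed_b = 302L)
  spec <- model_spec("rf", cv_folds = 5L, cv_repeats = 2L, seed = 5)
  cx <- cross_examine(pair$a, pair$b, spec)
  for (rep in list(cx$a_to_b, cx$b_to_a)) {
    expect_gte(rep$sensitivity, 0.95)
    expect_gte(rep$specificity, 0.95)
    expect_gte(rep$auc, 0.95)
  }
  # OLK rows are scored but never fitted on
  olk_row <- feature_table(matrix(c(1L, 1L, rep(0L, 8)), 1), "k", "KX")
  a_olk <- feature_table(rbind(feature_counts(pair$a), feature_counts(olk_row)),
                         c(pair$a$label, "k"), c(pair$a$case_id, "KX"))
  cx2 <- cross_examine(a_olk, pair$b, spec)
  expect_identical(cx2$models$a$class_counts, cx$models$a$class_counts)
})

test_that("resubstitution is at least as optimistic as holdout", {
  pair <- synthetic_cohort_pair(20L, seed_a = 501L, seed_b = 502L)
  spec <- model_spec("rf", cv_folds = 5L, cv_repeats = 1L, seed = 8)
  resub <- cross_examine(pair$a, pair$a, spec)   # test set = training cohort
  cross <- cross_examine(pair$a, pair$b, spec)
  expect_gte(resub$a_to_b$auc, cross$a_to_b$auc - 1e-9)
})

test_that("mean OSCC OCRI2 does not fall as aneuploid prevalence rises", {
  train <- synthetic_cohort_pair(25L, seed_a = 601L, seed_b = 602L)
  spec <- model_spec("rf", cv_folds = 5L, cv_repeats = 1L, seed = 6)
  model <- tune_and_train(train$a, spec)
  # isolate the prevalence dial: the variant profile shares the normal
  # base mixture, so only the planted aneuploid component separates a
  # carrier case from a normal one
  base <- group_profile("normal")$components
  mean_risk <- vapply(c(0.5, 0.75, 1.0), function(prev) {
    prof <- group_profile("oscc", components = base,
                          aneuploid_prevalence = prev)
    co <- simulate_cohort(cohort_spec(c(oscc = 100), seed = 99,
                                      profiles = list(oscc = prof)))
    ft <- reconstruct_dataset(co)
    mean(compute_ocri2(model, ft))
  }, numeric(1))
  expect_true(all(diff(mean_risk) >= -1e-9))
})
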