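test_that("leave-one-out folds partition the cohort", {
  ids <- sprintf("S%03d", 1:121)
  folds <- make_loocv_folds(ids)
  expect_length(folds, 121L)
  tests <- vapply(folds, function(f) f$test_index, integer(1))
  expect_setequal(tests, 1:121)
  expect_true(all(vapply(folds, function(f) {
    length(f$train_index) == 120L && !(f$test_index %in% f$train_index)
  }, logical(1))))
  f2 <- make_loocv_folds(c("a", "b"))
  expect_length(f2, 2L)
  expect_error(make_loocv_folds("a"), "at least 2")
})

test_that("univariate ranking: tie rule, constants, and k = all", {
  tb <- binary_cohort(10, 10, zero_effect(), seed = 51)
  tb$superficial_ST <- tb$superficial_IT  # duplicated column
  tb$choroid_T <- 5  # constant feature
  rk <- rank_features_univariate(tb, task_labels(tb, "diagnosis"))
  expect_equal(nrow(rk), 42L)
  # duplicated columns share a p-value and sit adjacent in canonical order
  ri <- which(rk$feature %in% c("superficial_ST", "superficial_IT"))
  expect_equal(diff(ri), 1L)
  expect_lt(ri[1], ri[2])
  expect_equal(rk$feature[ri], c("superficial_ST", "superficial_IT"))
  # constant feature has p = 1 and ranks last (ties after it share p = 1)
  expect_equal(rk$p_value[rk$feature == "choroid_T"], 1)
  expect_equal(rk$p_value[42], 1)
})

test_that("no leakage: training artifacts ignore the held-out subject", {
  tb <- binary_cohort(8, 8, deficit_effect("superficial_IT", -40), seed = 61)
  poisoned <- tb
  poisoned[3, feature_columns()] <- 999
  # fixed k so the (global, test-set-driven) k choice cannot differ
  cv1 <- run_nested_evaluation(tb, "diagnosis", "svm", grid = linear_grid(),
                               feature_set = "selected", k_grid = 5,
                               seed = 4)
  cv2 <- run_nested_evaluation(poisoned, "diagnosis", "svm",
                               grid = linear_grid(), feature_set = "selected",
                               k_grid = 5, seed = 4)
  # fold 3 trains without subject 3: identical ranking and hyperparameters
  expect_identical(cv1$per_fold[[3]]$features, cv2$per_fold[[3]]$features)
  expect_identical(cv1$per_fold[[3]]$params, cv2$per_fold[[3]]$params)
})

test_that("accuracy-vs-k curve covers the k grid and picks the argmax", {
  tb <- binary_cohort(8, 8, deficit_effect("superficial_IT", -50), seed = 62)
  cv <- run_nested_evaluation(tb, "diagnosis", "svm",
                              grid = linear_grid(1), feature_set = "selected",
                              k_grid = c(1, 3, 7), seed = 2)
  expect_equal(cv$accuracy_by_k$k, c(1, 3, 7))
  expect_equal(cv$chosen_k,
               cv$accuracy_by_k$k[which.max(cv$accuracy_by_k$accuracy)])
  expect_equal(cv$n_folds, 16L)
  expect_false(any(is.na(cv$predictions)))
})

test_that("full selected-mode curve has 42 points by default", {
  tb <- binary_cohort(5, 5, deficit_effect("superficial_IT", -60), seed = 63)
  cv <- run_nested_evaluation(tb, "diagnosis", "svm", grid = linear_grid(1),
                              feature_set = "selected", inner_folds = 2,
                              seed = 2)
  expect_equal(nrow(cv$accuracy_by_k), 42L)
})

test_that("single-feature mode supports the S-IT and RNFL baselines", {
  tb <- binary_cohort(10, 10, deficit_effect("superficial_IT", -60),
                      seed = 64)
  cv <- run_nested_evaluation(tb, "diagnosis", "svm", grid = linear_grid(1),
                              feature_set = "S-IT", seed = 3)
  expect_identical(cv$per_fold[[1]]$features, "superficial_IT")
  cvr <- run_nested_evaluation(tb, "diagnosis", "svm", grid = linear_grid(1),
                               feature_set = "RNFL", seed = 3)
  expect_identical(cvr$per_fold[[1]]$features, "rnfl_um")
  expect_error(run_nested_evaluation(tb, "diagnosis", "svm",
                                     feature_set = "nope"), "unknown feature")
})

test_that("a perfectly separating single feature yields AUROC exactly 1", {
  tb <- binary_cohort(10, 10, zero_effect(), seed = 65, feature_sd = 1)
  tb$superficial_IT <- ifelse(tb$label == "glaucoma", 10, 200)
  cv <- run_nested_evaluation(tb, "diagnosis", "svm", grid = linear_grid(1),
                              feature_set = "S-IT", seed = 3)
  expect_identical(auroc(cv$scores, cv$truth == "glaucoma"), 1)
})

test_that("outer AUROC is non-decreasing in the synthetic effect size", {
  aucs <- vapply(c(0, 1, 2, 3), function(k) {
    tb <- binary_cohort(15, 15, deficit_effect("superficial_IT", -k * 17),
                        seed = 70 + k)
    cv <- run_nested_evaluation(tb, "diagnosis", "svm", grid = linear_grid(1),
                                feature_set = "S-IT", seed = 5)
    auroc(cv$scores, cv$truth == "glaucoma")
  }, numeric(1))
  expect_lte(sum(diff(aucs) < 0), 1)  # at most one inversion
  expect_gt(aucs[4], aucs[1])
})

test_that("nested evaluation is reproducible for a fixed master seed", {
  tb <- binary_cohort(8, 8, deficit_effect("superficial_IT", -40), seed = 81)
  cv1 <- run_nested_evaluation(tb, "diagnosis", "rf", grid = tiny_rf_grid(),
                               feature_set = "all", seed = 11)
  cv2 <- run_nested_evaluation(tb, "diagnosis", "rf", grid = tiny_rf_grid(),
                               feature_set = "all", seed = 11)
  expect_identical(cv1$scores, cv2$scores)
  expect_identical(cv1$predictions, cv2$predictions)
})

test_that("multiclass severity task runs one-versus-all with score matrix", {
  sp <- cohort_effect_spec(n_per_group = c(control = 6, mild = 6,
                                           moderate = 6, severe = 6),
                           seed = 91)
  tb <- generate_cohort_feature_table(sp)
  cv <- run_nested_evaluation(tb, "severity", "svm", grid = linear_grid(1),
                              feature_set = "all", seed = 2)
  expect_equal(dim(cv$scores), c(24L, 4L))
  expect_equal(colnames(cv$scores),
               c("control", "mild", "moderate", "severe"))
  rep <- score_multiclass(cv, n_boot = 1000, seed = 1)
  expect_true(all(rep$estimate >= 0 & rep$estimate <= 1))
  expect_true(all(rep$ci_low <= rep$estimate & rep$estimate <= rep$ci_high))
  cm <- attr(rep, "confusion")
  expect_equal(unname(rowSums(cm)), rep(6L, 4L))
})

test_that("micro-averaged sensitivity equals accuracy on random tables", {
  set.seed(17)
  for (i in 1:20) {
    lev <- c("control", "mild", "moderate", "severe")
    truth <- factor(sample(lev, 60, replace = TRUE), levels = lev)
    pred <- factor(sample(lev, 60, replace = TRUE), levels = lev)
    acc <- mean(pred == truth)
    tp <- sum(vapply(lev, function(cl) sum(pred == cl & truth == cl),
                     numeric(1)))
    fn <- sum(vapply(lev, function(cl) sum(pred != cl & truth == cl),
                     numeric(1)))
    expect_equal(tp / (tp + fn), acc, tolerance = 1e-12)
  }
})

test_that("perfect multiclass predictions give all metrics 1", {
  lev <- c("control", "mild", "moderate", "severe")
  truth <- factor(rep(lev, each = 10), levels = lev)
  scores <- vapply(lev, function(cl) as.numeric(truth == cl),
                   numeric(length(truth)))
  rep <- score_multiclass(truth = truth, pred = truth, scores = scores,
                          n_boot = 1000, seed = 1)
  expect_equal(rep$estimate, rep(1, 4))
  cm <- attr(rep, "confusion")
  expect_true(all(cm[row(cm) != col(cm)] == 0))
})

test_that("binary metrics report respects its invariants", {
  tb <- binary_cohort(10, 10, deficit_effect("superficial_IT", -50),
                      seed = 95)
  cv <- run_nested_evaluation(tb, "diagnosis", "svm", grid = linear_grid(1),
                              feature_set = "all", seed = 7)
  rep <- score_binary(cv, n_boot = 1000, seed = 2)
  expect_equal(rep$metric, c("auroc", "accuracy", "sensitivity",
                             "specificity"))
  expect_true(all(rep$estimate >= 0 & rep$estimate <= 1))
  expect_true(all(rep$ci_low <= rep$estimate & rep$estimate <= rep$ci_high))
})
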