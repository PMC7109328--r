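test_that("classifier specs validate hyperparameters against their schema", {
  expect_s3_class(classifier_spec("random_forest", ntree = 50, seed = 1),
                  "classifier_spec")
  expect_error(classifier_spec("random_forest", k = 3), "unknown hyperparameter")
  expect_error(classifier_spec("knn", k = 0), "k must be")
  expect_error(classifier_spec("svm", kernel = "wavelet"), "kernel")
  expect_error(classifier_spec("boosting"), "arg")
})

test_that("every classifier family fits, scores in [0,1] and predicts labels", {
  fm <- separable_features(25, seed = 3, length_range = c(60, 120))
  labels <- attr(fm, "labels")
  for (family in c("random_forest", "c45_tree", "naive_bayes", "svm", "knn")) {
    model <- fit_classifier(fm, spec = classifier_spec(family, seed = 4))
    sc <- predict(model, fm, type = "score")
    expect_true(all(sc >= 0 & sc <= 1), info = family)
    cl <- predict(model, fm, type = "class")
    expect_true(all(cl %in% c("positive", "negative")), info = family)
    # strongly biased composition: near-perfect resubstitution for all families
    expect_gte(mean(cl == labels), 0.9)
  }
  expect_error(fit_classifier(fm, labels = rep("positive", nrow(fm)),
                              spec = classifier_spec("svm")),
               "both classes")
})

test_that("cross-validation is stratified, deterministic and pools fold counts", {
  fm <- separable_features(20, seed = 6, length_range = c(50, 100))
  spec <- classifier_spec("naive_bayes", seed = 2)
  r1 <- cross_validate(fm, spec, folds = 5, seed = 11)
  r2 <- cross_validate(fm, spec, folds = 5, seed = 11)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$folds, r2$folds)
  expect_equal(sum(r1$folds$tp + r1$folds$tn + r1$folds$fp + r1$folds$fn),
               nrow(fm))
  # every fold holds 4+4 samples (20 per class over 5 folds)
  per_fold_n <- rowSums(r1$folds[, c("tp", "tn", "fp", "fn")])
  expect_true(all(per_fold_n == 8))
})

test_that("fold class proportions deviate from global by at most one sample", {
  set.seed(13)
  y <- factor(c(rep("positive", 23), rep("negative", 41)),
              levels = c("negative", "positive"))
  fid <- abctk:::stratified_folds(y, folds = 7, seed = 5)
  for (f in 1:7) {
    n_pos <- sum(y[fid == f] == "positive")
    expect_true(abs(n_pos - 23 / 7) < 1)
  }
})

test_that("cross-validation rejects invalid inputs", {
  fm <- separable_features(10, seed = 1, length_range = c(40, 60))
  expect_error(cross_validate(fm, folds = 1, seed = 1), "folds")
  expect_error(cross_validate(fm, folds = 11, seed = 1), "minority")
  expect_error(cross_validate(fm, folds = 5), "seed")
  one_class <- fm
  attr(one_class, "labels") <- rep("positive", nrow(fm))
  expect_error(cross_validate(one_class, folds = 2, seed = 1), "both classes")
})

test_that("a separable fixture yields a perfect cross-validated random forest", {
  fm <- separable_features(30, seed = 17)
  r <- cross_validate(fm, classifier_spec("random_forest", seed = 3),
                      folds = 5, seed = 23)
  expect_equal(r$acc, 1)
  expect_equal(r$mcc, 1)
  expect_equal(r$auc, 1)
})

test_that("randomly permuted labels give chance-level AUC", {
  fm <- separable_features(250, seed = 29, delta = 0.3)
  set.seed(31)
  attr(fm, "labels") <- sample(attr(fm, "labels"))
  r <- cross_validate(fm, classifier_spec("random_forest", seed = 1),
                      folds = 10, seed = 37)
  expect_gte(r$auc, 0.4)
  expect_lte(r$auc, 0.6)
})

test_that("hold-out evaluation on negative-only test sets reports specificity and flags the rest", {
  fm <- separable_features(25, seed = 41, length_range = c(60, 120))
  model <- fit_classifier(fm, spec = classifier_spec("random_forest", seed = 2))
  pool <- generate_dataset(synthetic_spec(n_positive = 2, n_negative = 30,
                                          length_range = c(60, 120),
                                          delta = 0.3, seed = 43))
  test_fm <- encode_dataset(pool$negatives)
  r <- evaluate_holdout(model, test_fm)
  expect_equal(r$level, "holdout")
  expect_equal(r$acc, r$sp)   # negative-only: accuracy IS specificity
  expect_true(all(c("sn", "mcc") %in% r$undefined))
  expect_null(r$auc)
  expect_error(evaluate_holdout(model, test_fm[0, , drop = FALSE],
                                labels = character(0)), "empty test")
  expect_error(predict(model, test_fm[, 1:50]), "mismatch")
})

test_that("mixed hold-out evaluation recovers the full metric panel", {
  fm <- separable_features(40, seed = 47)
  model <- fit_classifier(fm, spec = classifier_spec("random_forest", seed = 2))
  test_fm <- separable_features(30, seed = 53)
  r <- evaluate_holdout(model, test_fm)
  expect_gte(r$acc, 0.95)
  expect_gte(r$auc, 0.95)
  expect_length(r$undefined, 0)
})

test_that("grid search returns the candidate with the best CV accuracy", {
  fm <- separable_features(15, seed = 59, length_range = c(40, 80))
  tuned <- tune_classifier(fm, "knn", grid = list(k = c(1L, 3L)),
                           folds = 3, seed = 61)
  expect_s3_class(tuned$spec, "classifier_spec")
  expect_equal(nrow(tuned$results), 2)
  best <- which.max(tuned$results$cv_accuracy)
  expect_equal(tuned$spec$hyperparameters$k, tuned$results$k[best])
})
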