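test_that("stratified folds balance classes and sizes and are seed-deterministic", {
  lab <- c(rep(1, 10), rep(0, 10))
  f <- stratified_folds(lab, k = 5, seed = 1)
  for (k in 1:5) {
    expect_equal(sum(lab[f == k] == 1), 2)
    expect_equal(sum(lab[f == k] == 0), 2)
  }

  # the 57/43 cohort shape: per-fold positives in {11,12}, negatives {8,9},
  # total fold sizes within 1 of each other
  lab2 <- c(rep(1, 57), rep(0, 43))
  f2 <- stratified_folds(lab2, k = 5, seed = 7)
  pos <- table(f2[lab2 == 1]); neg <- table(f2[lab2 == 0])
  expect_true(all(pos %in% c(11, 12)))
  expect_true(all(neg %in% c(8, 9)))
  expect_lte(diff(range(table(f2))), 1)

  expect_identical(stratified_folds(lab2, 5, seed = 7), f2)
  expect_false(identical(stratified_folds(lab2, 5, seed = 8), f2))
  expect_error(stratified_folds(rep(1, 10), 5),
               class = "serfe_validation_error")
  expect_error(stratified_folds(lab, 11), class = "serfe_validation_error")
})

test_that("confusion-matrix metrics follow the stated conventions", {
  m <- classification_metrics(tp = 45, fp = 15, tn = 35, fn = 5)
  expect_equal(m[["recall"]], 90)
  expect_equal(m[["specificity"]], 70)
  expect_equal(m[["balanced_accuracy"]], 80)
  expect_equal(m[["precision"]], 75)

  perfect <- classification_metrics(10, 0, 10, 0)
  expect_true(all(perfect[c("recall", "precision", "balanced_accuracy", "f1")] == 100))

  degen <- classification_metrics(0, 0, 10, 10)
  expect_equal(degen[["precision"]], 0)
  expect_equal(degen[["f1"]], 0)
  expect_equal(degen[["balanced_accuracy"]], 50)

  expect_error(classification_metrics(0, 0, 0, 0),
               class = "serfe_validation_error")
})

test_that("rank-based AUC matches enumeration and tie conventions", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.4), c(1, 1, 0, 0))$auc, 1.0)
  # pos {0.9, 0.3}, neg {0.7, 0.4}: 2 of 4 pairs concordant
  expect_equal(roc_auc(c(0.9, 0.3, 0.7, 0.4), c(1, 1, 0, 0))$auc, 0.5)
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), class = "serfe_validation_error")

  # curve starts at (0,0), ends at (1,1), and is monotone
  r <- roc_auc(rnorm(50), rbinom(50, 1, 0.5))
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(tail(r$curve$fpr, 1), 1)
  expect_equal(tail(r$curve$tpr, 1), 1)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
})

test_that("AUC equals the all-pairs concordance count on random instances", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    lab <- c(1, 0, rbinom(n - 2, 1, 0.5))       # both classes guaranteed
    sc <- round(rnorm(n), sample(0:2, 1))       # rounding induces ties
    expect_equal(roc_auc(sc, lab)$auc, auc_bruteforce(sc, lab),
                 tolerance = 1e-12)
  }
})

test_that("standardization statistics come from the training fold only", {
  set.seed(12)
  train <- matrix(rnorm(50), 10)
  test <- matrix(rnorm(25), 5)
  std <- serfe:::fit_standardizer(train)
  spiked <- test; spiked[1, 1] <- 1e6
  # spiking the held-out fold cannot change the fitted statistics
  expect_identical(std, serfe:::fit_standardizer(train))
  z <- serfe:::apply_standardizer(std, spiked)
  expect_equal(z[-1, ], serfe:::apply_standardizer(std, test)[-1, ])
  # constant training columns get unit scale, not NaN
  const <- matrix(c(rep(1, 5), rnorm(5)), 5)
  z2 <- serfe:::apply_standardizer(serfe:::fit_standardizer(const), const)
  expect_true(all(is.finite(z2)))
})

test_that("null cohorts score at chance and planted signal is recovered", {
  # average over replicate null cohorts to shrink the Monte-Carlo error of
  # the chance-level estimate (a single null AUC draw has sd ~ 0.06)
  null_runs <- lapply(1:3, function(i) {
    co <- generate_cohort(synthetic_cohort_spec(
      n_patients = 200, class_effect = 0, seed = 31 + i))
    evaluate_classifiers(co$features, config = serfe_config(seed = 31 + i))
  })
  for (cl in c("svm", "random_forest", "knn")) {
    ba <- mean(vapply(null_runs, function(r)
      r$classifiers[[cl]]$mean[["balanced_accuracy"]], numeric(1)))
    auc <- mean(vapply(null_runs, function(r)
      r$classifiers[[cl]]$auc, numeric(1)))
    expect_lt(abs(ba - 50), 7)
    expect_lt(abs(auc - 0.5), 0.08)
  }

  sig_co <- generate_cohort(synthetic_cohort_spec(
    n_patients = 200, class_effect = 2.0, n_informative = 20, seed = 32))
  rep1 <- evaluate_classifiers(sig_co$features,
                               config = serfe_config(seed = 32))
  expect_gte(rep1$classifiers$random_forest$mean[["balanced_accuracy"]], 85)
  expect_gt(rep1$classifiers$random_forest$auc, 0.9)

  # label permutation re-centres all classifiers at chance
  set.seed(33)
  perm <- sample(sig_co$features$labels)
  names(perm) <- names(sig_co$features$labels)
  repp <- evaluate_classifiers(sig_co$features, labels = perm,
                               config = serfe_config(seed = 33))
  for (cl in names(repp$classifiers))
    expect_lt(abs(repp$classifiers[[cl]]$mean[["balanced_accuracy"]] - 50), 7)
})

test_that("evaluation is reproducible for a fixed seed and duplication-stable", {
  co <- generate_cohort(synthetic_cohort_spec(n_patients = 80, seed = 41))
  a <- evaluate_classifiers(co$features, config = serfe_config(seed = 5))
  b <- evaluate_classifiers(co$features, config = serfe_config(seed = 5))
  for (cl in names(a$classifiers)) {
    expect_identical(a$classifiers[[cl]]$folds, b$classifiers[[cl]]$folds)
    expect_identical(a$classifiers[[cl]]$auc, b$classifiers[[cl]]$auc)
  }

  # duplicating every patient cannot degrade the metrics (a duplicate of a
  # test patient may land in training, which only helps), and keeps them in
  # the valid range
  v2 <- rbind(co$features$values, co$features$values)
  rownames(v2) <- sprintf("P%04d", seq_len(nrow(v2)))
  lab2 <- rep(unname(co$features$labels), 2)
  dup <- feature_matrix(v2, labels = lab2)
  rd <- evaluate_classifiers(dup, config = serfe_config(seed = 5),
                             classifiers = "svm")
  expect_gte(rd$classifiers$svm$mean[["balanced_accuracy"]],
             a$classifiers$svm$mean[["balanced_accuracy"]] - 5)
  expect_lte(rd$classifiers$svm$mean[["balanced_accuracy"]], 100)
})
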