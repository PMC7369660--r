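test_that("confusion metrics match the direct formulas", {
  y_true <- c(rep("malignant", 4), rep("benign", 6))
  y_pred <- c("malignant", "malignant", "malignant", "benign",
              "malignant", rep("benign", 5))
  m <- confusion_metrics(y_true, y_pred)
  expect_equal(unname(m["accuracy"]), 0.8)
  expect_equal(unname(m["precision"]), 0.75)
  expect_equal(unname(m["sensitivity"]), 0.75)
  expect_equal(unname(m["specificity"]), 5 / 6)
  expect_equal(unname(m[c("tp", "fp", "tn", "fn")]), c(3, 1, 5, 1))
  # perfect prediction
  p <- confusion_metrics(y_true, y_true)
  expect_equal(unname(p[1:4]), rep(1, 4))
  # all-positive predictor
  ap <- confusion_metrics(y_true, rep("malignant", 10))
  expect_equal(unname(ap["sensitivity"]), 1)
  expect_equal(unname(ap["specificity"]), 0)
  # missing class in truth: flagged NA, no NaN
  one <- confusion_metrics(rep("malignant", 3), rep("malignant", 3))
  expect_true(is.na(one["specificity"]))
  expect_true("specificity" %in% attr(one, "undefined"))
})

test_that("ROC sweep yields the documented curve shape and AUC values", {
  y <- c("malignant", "malignant", "benign", "benign")
  r <- roc_curve(y, c(0.9, 0.4, 0.8, 0.3))
  expect_equal(r$auc, 0.75)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[length(r$fpr)], 1)
  expect_equal(r$tpr[length(r$tpr)], 1)
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
  # perfect separation and all-tied scores
  expect_equal(roc_auc(y, c(5, 4, 2, 1)), 1)
  expect_equal(roc_auc(y, rep(1, 4)), 0.5)
  expect_error(roc_curve(rep("malignant", 3), 1:3), "both classes")
})

test_that("sweep AUC equals the Mann-Whitney pair statistic", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    y <- sample(c("benign", "malignant"), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c("benign", "malignant")
    sc <- round(rnorm(n), sample(0:2, 1))  # induce ties
    expect_equal(roc_auc(y, sc), oracle_auc_mw(y == "malignant", sc),
                 tolerance = 1e-12)
  }
})

test_that("ROC is invariant under strictly monotone score transforms", {
  set.seed(24)
  y <- sample(c("benign", "malignant"), 50, replace = TRUE)
  y[1:2] <- c("benign", "malignant")
  sc <- rnorm(50)
  r1 <- roc_curve(y, sc)
  r2 <- roc_curve(y, exp(2 * sc) + 1)
  expect_equal(r1$fpr, r2$fpr)
  expect_equal(r1$tpr, r2$tpr)
  expect_equal(r1$auc, r2$auc, tolerance = 1e-12)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(25)
  y <- sample(c("benign", "malignant"), 80, replace = TRUE)
  y[1:2] <- c("benign", "malignant")
  sc <- rnorm(80)
  ref <- suppressMessages(
    as.numeric(pROC::auc(pROC::roc(y, sc, levels = c("benign", "malignant"),
                                   direction = "<"))))
  expect_equal(roc_auc(y, sc), ref, tolerance = 1e-12)
})

separable_table <- function(n = 40, seed = 3) {
  set.seed(seed)
  label <- factor(rep(c("benign", "malignant"), each = n / 2))
  data.frame(f1 = rnorm(n, ifelse(label == "malignant", 4, 0), 0.5),
             f2 = rnorm(n, ifelse(label == "malignant", -3, 0), 0.5),
             f3 = rnorm(n), label = label)
}

test_that("cross-validation is perfect on separable data, seeded-stable", {
  tab <- separable_table()
  for (clf in c("svm", "dt", "knn", "nb")) {
    ev <- cross_validate(tab, clf, folds = 10, seed = 5)
    expect_equal(unname(ev$mean["accuracy"]), 1,
                 tolerance = 1e-12, label = clf)
    expect_equal(unname(ev$sd["accuracy"]), 0, tolerance = 1e-12)
  }
  e1 <- cross_validate(tab, "svm", folds = 10, seed = 9, select_k = 2)
  e2 <- cross_validate(tab, "svm", folds = 10, seed = 9, select_k = 2)
  expect_identical(e1$per_fold, e2$per_fold)
  expect_identical(e1$roc$auc, e2$roc$auc)
})

test_that("label-permuted data scores near the majority-class rate", {
  tab <- separable_table(n = 60, seed = 6)
  set.seed(60)
  tab$label <- sample(tab$label)
  accs <- sapply(c("svm", "knn", "nb"), function(clf)
    cross_validate(tab, clf, folds = 10, seed = 7)$mean["accuracy"])
  # chance level 0.5; allow generous monte-carlo spread (3 sd of a
  # binomial mean over 60 held-out samples is about 0.19)
  expect_true(all(abs(accs - 0.5) < 0.2))
})

test_that("fold handling: reduction warning, class and protocol errors", {
  tab <- separable_table(n = 12)
  expect_warning(ev <- cross_validate(tab, "nb", folds = 10, seed = 1),
                 "reducing folds")
  expect_identical(ev$folds, 6L)
  bad <- separable_table(n = 10)
  bad$label <- factor(rep("benign", 10))
  expect_error(cross_validate(bad, "svm"), "two classes")
})

test_that("holdout evaluation reserves the requested stratified fraction", {
  tab <- separable_table(n = 40)
  ho <- holdout_evaluate(tab, "svm", test_fraction = 0.2, seed = 8)
  expect_length(ho$test_idx, 8)
  expect_equal(unname(ho$metrics["accuracy"]), 1)
  expect_equal(ho$auc, 1)
})

test_that("paper-mode fits preprocessing once on the full table", {
  tab <- separable_table(n = 40)
  ev <- cross_validate(tab, "knn", folds = 5, seed = 2, select_k = 2,
                       paper_mode = TRUE)
  expect_equal(unname(ev$mean["accuracy"]), 1)
})
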