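test_that("confusion arithmetic reproduces the printed test-set metrics", {
  # SMOTE arm: TN=32, FP=3, FN=2, TP=4
  r <- report_from_confusion(tn = 32, fp = 3, fn = 2, tp = 4)
  expect_equal(r$accuracy, 36 / 41)
  expect_equal(round(100 * r$accuracy), 88)
  expect_equal(r$specificity, 32 / 35)
  expect_equal(round(r$specificity, 2), 0.91)
  expect_equal(r$sensitivity, 4 / 6)
  expect_equal(r$weighted_recall, r$accuracy)
  expect_equal(round(r$weighted_f1, 2), 0.88)
  # downsampling arm: TN=28, FP=7, FN=0, TP=6
  r2 <- report_from_confusion(tn = 28, fp = 7, fn = 0, tp = 6)
  expect_equal(round(100 * r2$accuracy), 83)
  expect_equal(round(100 * r2$specificity), 80)
  expect_equal(r2$sensitivity, 1)
})

test_that("balanced accuracy identity and undefined rates", {
  set.seed(2)
  for (k in 1:50) {
    cm <- rmultinom(1, 60, rep(0.25, 4))
    r <- report_from_confusion(cm[1], cm[2], cm[3], cm[4])
    if (!is.na(r$sensitivity) && !is.na(r$specificity)) {
      expect_equal(r$balanced_accuracy, (r$sensitivity + r$specificity) / 2,
                   tolerance = 1e-12)
    }
    expect_true(all(unlist(r[c("sensitivity", "specificity", "ppv", "npv",
                               "accuracy", "weighted_f1")]) >= 0, na.rm = TRUE))
  }
  # no predicted positives: PPV undefined, not zero
  r0 <- report_from_confusion(tn = 30, fp = 0, fn = 5, tp = 0)
  expect_true(is.na(r0$ppv))
  expect_equal(r0$specificity, 1)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(7)
  y <- rbinom(100, 1, 0.4)
  s <- rnorm(100) + y
  a1 <- auc_trapezoid(s, y)
  expect_equal(auc_trapezoid(exp(s), y), a1, tolerance = 1e-12)
  expect_equal(auc_trapezoid(qlogis(plogis(s)), y), a1, tolerance = 1e-10)
  expect_equal(auc_trapezoid(rank(s), y), a1, tolerance = 1e-12)
  # perfect separation gives AUC 1; degenerate labels error
  expect_equal(auc_trapezoid(y + 1, y), 1)
  expect_error(auc_trapezoid(s, rep(1, 100)), "single class")
})

test_that("AUC agrees with the Mann-Whitney statistic including ties", {
  set.seed(12)
  y <- rbinom(200, 1, 0.3)
  s <- round(rnorm(200) + 0.8 * y, 1)   # heavy ties
  pos <- s[y == 1]; neg <- s[y == 0]
  mw <- (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
  expect_equal(auc_trapezoid(s, y), mw, tolerance = 1e-12)
})

test_that("perfect classifier yields all rates 1 and AUC 1", {
  fm <- gbt_fixture()$fm
  y <- fm$y
  X <- cbind(perfect = as.numeric(y), noise = rnorm(length(y)))
  fm2 <- structure(list(X = X, y = y,
                        meta = data.frame(name = colnames(X), source = colnames(X),
                                          group = "ecrf", binary = c(TRUE, FALSE))),
                   class = "feature_matrix")
  m <- gbt_fit(fm2, n_estimators = 20)
  r <- evaluate(m, fm2)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$auc, 1)
})

test_that("cross-validation folds are stratified and the mean row is the fold mean", {
  fm <- gbt_fixture()$fm
  cv <- cross_validate(fm, n_folds = 5, imbalance_method = "smote", seed = 3,
                       n_estimators = 30)
  sz <- table(cv$fold_assignment)
  expect_lte(max(sz) - min(sz), 1)
  for (nm in names(cv$mean)) {
    expect_equal(unname(cv$mean[nm]), mean(cv$folds[[nm]]), tolerance = 1e-12)
  }
})

test_that("five folds on a 160-row balanced set have 32 rows each", {
  fm <- gbt_fixture()
  bal <- fm$train_bal
  # SMOTE-balanced training set: 80 + 80 = 160 rows
  expect_equal(length(bal$y), 160)
  fold <- carotidrisk:::stratified_folds(bal$y, 5, seed = 1)
  expect_true(all(table(fold) == 32))
})

test_that("imbalance correction happens inside training folds only", {
  fm <- gbt_fixture()$split$train
  cv <- cross_validate(fm, n_folds = 5, imbalance_method = "undersample", seed = 2,
                       n_estimators = 20)
  # validation folds keep the original (imbalanced) composition: fold sizes
  # reflect the 80/13 train partition, not a balanced set
  expect_equal(sum(cv$folds$tn + cv$folds$fp + cv$folds$fn + cv$folds$tp), 93)
})
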