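sim_dataset <- function(n, p = 6, seed = 1, beta = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), ncol = p, dimnames = list(NULL, paste0("x", seq_len(p))))
  if (is.null(beta)) beta <- c(1.5, -1, 0.8, rep(0, p - 3))
  y <- rbinom(n, 1, plogis(X %*% beta))
  structure(list(X = X, y = as.integer(y),
                 meta = data.frame(name = colnames(X), source = colnames(X),
                                   group = "ecrf", binary = FALSE)),
            class = "feature_matrix")
}

test_that("base score is the log-odds of the training prevalence", {
  fm <- sim_dataset(100)
  fm$y <- rep(c(0L, 1L), 50)
  m <- gbt_fit(fm, n_estimators = 1)
  expect_equal(m$f0, 0)
  fm$y <- c(rep(0L, 80), rep(1L, 20))
  m2 <- gbt_fit(fm, n_estimators = 1)
  expect_equal(m2$f0, qlogis(0.2))
})

test_that("first-stage pseudo-residual for y=1 at F0=0 is 0.5", {
  # r = y - sigmoid(F0); with balanced classes F0 = 0
  expect_equal(1 - plogis(0), 0.5)
  # model with zero trees predicts sigmoid(F0) everywhere
  fm <- sim_dataset(60)
  fm$y <- rep(c(0L, 1L), 30)
  m <- gbt_fit(fm, n_estimators = 1)
  m$trees <- list()
  pr <- gbt_predict(m, fm)
  expect_equal(pr$prob, rep(0.5, 60))
})

test_that("training log loss is non-increasing across stages", {
  for (s in 1:20) {
    fm <- sim_dataset(80, seed = s)
    m <- gbt_fit(fm, n_estimators = 30, learning_rate = 0.1, max_depth = 3)
    expect_true(all(diff(m$train_loss) <= 1e-10))
  }
})

test_that("probabilities stay inside (0,1) and threshold sets the class", {
  fm <- sim_dataset(150, seed = 9)
  m <- gbt_fit(fm, n_estimators = 50)
  pr <- gbt_predict(m, fm)
  expect_true(all(pr$prob > 0 & pr$prob < 1))
  expect_equal(pr$class, as.integer(pr$prob >= 0.5))
  pr2 <- gbt_predict(m, fm, threshold = 0.9)
  expect_true(all(pr2$class <= pr$class))
})

test_that("linearly separable data is fit to high training accuracy", {
  set.seed(4)
  n <- 120
  X <- matrix(rnorm(n * 4), ncol = 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- as.integer(X[, 1] + X[, 2] > 0)
  fm <- structure(list(X = X, y = y,
                       meta = data.frame(name = colnames(X), source = colnames(X),
                                         group = "ecrf", binary = FALSE)),
                  class = "feature_matrix")
  m <- gbt_fit(fm, n_estimators = 100, learning_rate = 0.1, max_depth = 3)
  acc <- mean(gbt_predict(m, fm)$class == y)
  expect_gte(acc, 0.95)
})

test_that("column mismatch is rejected and single-class training errors", {
  fm <- sim_dataset(50)
  m <- gbt_fit(fm, n_estimators = 5)
  bad <- fm$X
  colnames(bad) <- paste0("z", seq_len(ncol(bad)))
  expect_error(gbt_predict(m, bad), "feature columns")
  fm1 <- fm; fm1$y <- rep(0L, 50)
  expect_error(gbt_fit(fm1), "both classes")
})

test_that("model JSON round trip preserves predictions", {
  fm <- sim_dataset(60, seed = 2)
  m <- gbt_fit(fm, n_estimators = 10)
  path <- file.path(tempdir(), "gbt.json")
  write_gbt_json(m, path)
  m2 <- read_gbt_model(path)
  expect_equal(gbt_predict(m2, fm)$prob, gbt_predict(m, fm)$prob, tolerance = 1e-12)
})

test_that("from-scratch GBT matches the reference implementation's test AUC", {
  res <- sklearn_gbt_oracle(n_datasets = 3, n_train = 150, n_test = 250, p = 8)
  expect_lt(max(abs(res$auc_ours - res$auc_ref)), 0.02)
  expect_lt(max(res$prob_median_absdiff), 0.05)
})
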