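linear_margin <- function(beta) {
  function(X) as.numeric(X %*% beta)
}

test_that("exact Shapley satisfies the efficiency axiom", {
  fx <- small_model_fixture()
  att <- exact_shapley(fx$model, fx$X_explain, fx$background)
  resid <- rowSums(att$values) - (att$margins - att$baseline)
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("a feature the model never uses gets zero attribution (null player)", {
  fx <- small_model_fixture()
  # linear model ignoring feature 4
  beta <- c(1, -2, 0.5, 0, 0.3, 0, 0, 0)
  att <- exact_shapley(linear_margin(beta), fx$X_explain, fx$background)
  expect_lt(max(abs(att$values[, 4])), 1e-10)
  expect_lt(max(abs(att$values[, 7])), 1e-10)
  expect_gt(min(abs(att$values[, 1])), 0)
})

test_that("duplicated symmetric features receive equal attributions", {
  set.seed(40)
  X <- matrix(rnorm(40 * 4), ncol = 4, dimnames = list(NULL, paste0("x", 1:4)))
  X[, 2] <- X[, 1]                      # duplicated feature
  bg <- X[21:40, , drop = FALSE]
  f <- function(M) M[, 1] + M[, 2] + 0.5 * M[, 3]   # symmetric use of x1, x2
  att <- exact_shapley(f, X[1:10, ], bg)
  expect_lt(max(abs(att$values[, 1] - att$values[, 2])), 1e-8)
})

test_that("sampled estimator agrees with exact enumeration within 3 SE", {
  fx <- small_model_fixture()
  exact <- exact_shapley(fx$model, fx$X_explain, fx$background)
  samp <- sampled_shapley(fx$model, fx$X_explain, fx$background,
                          n_permutations = 2000, seed = 5)
  gap <- abs(samp$values - exact$values)
  bound <- 3 * samp$se + 1e-10
  expect_true(all(gap <= pmax(bound, 3e-3)))
  # permutation telescoping makes efficiency hold for the sampled version too
  resid <- rowSums(samp$values) - (samp$margins - samp$baseline)
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("sampled estimator variance shrinks like 1/n_permutations", {
  fx <- small_model_fixture()
  npl <- c(25, 100, 400)
  v <- sapply(npl, function(np) {
    ests <- sapply(1:8, function(s) {
      sampled_shapley(fx$model, fx$X_explain[1, , drop = FALSE], fx$background,
                      n_permutations = np, seed = s)$values[1, 1]
    })
    var(ests)
  })
  fit <- lm(log(v) ~ log(npl))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.35)
})

test_that("global importance ranks by mean |value| with stated invariances", {
  vals <- rbind(c(0.2, -1.5, 0.1), c(-0.4, 1.0, 0.05))
  colnames(vals) <- c("a", "b", "c")
  att <- structure(list(values = vals, baseline = 0, margins = rowSums(vals),
                        global_importance = colMeans(abs(vals)),
                        ranking = c("b", "a", "c")), class = "attribution_set")
  gi <- global_importance(att)
  expect_equal(gi$feature, c("b", "a", "c"))
  # homogeneity: scaling attributions scales importances, ranking unchanged
  att2 <- att; att2$values <- 2 * vals
  att2$global_importance <- colMeans(abs(att2$values))
  gi2 <- global_importance(att2)
  expect_equal(gi2$mean_abs_shap, 2 * gi$mean_abs_shap)
  expect_equal(gi2$feature, gi$feature)
  # all-zero attributions give all-zero importances with lexicographic ties
  att0 <- att; att0$values[] <- 0; att0$global_importance <- colMeans(abs(att0$values))
  gi0 <- global_importance(att0)
  expect_equal(gi0$mean_abs_shap, rep(0, 3))
  expect_equal(gi0$feature, c("a", "b", "c"))
})

test_that("dominant generative PSS effect is recovered as top importance", {
  spec0 <- generative_risk_spec(
    effects = c(pss = 2.5, smoking = 0.35, hypertension = 0.35, ica_stenosis_pct = 0.35,
                norm_area_high_osi = 0.3), seed = 1)
  hits <- 0
  n_runs <- 25
  for (s in seq_len(n_runs)) {
    spec <- spec0; spec$seed <- 500 + s
    d <- generate_cohort(spec)
    fm <- encode_features(d)
    bal <- smote_oversample(fm, seed = s)
    model <- gbt_fit(bal, n_estimators = 60)
    att <- sampled_shapley(model, fm$X[sample.int(nrow(fm$X), 12), , drop = FALSE],
                           fm$X[seq_len(40), , drop = FALSE],
                           n_permutations = 12, seed = s)
    if (global_importance(att)$feature[1] == "pss") hits <- hits + 1
  }
  expect_gte(hits / n_runs, 0.9)
})
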