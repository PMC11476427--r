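toy_fm <- function(n0, n1, p = 4, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm((n0 + n1) * p), ncol = p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  structure(list(X = X, y = c(rep(0L, n0), rep(1L, n1)),
                 meta = data.frame(name = paste0("f", seq_len(p)),
                                   source = paste0("f", seq_len(p)),
                                   group = "ecrf", binary = FALSE)),
            class = "feature_matrix")
}

test_that("stratified 70-30 split of 115/19 gives (80,13)/(35,6)", {
  fm <- toy_fm(115, 19)
  sp <- stratified_split(fm, test_fraction = 0.3, seed = 3)
  expect_equal(sum(sp$train$y == 0), 80)
  expect_equal(sum(sp$train$y == 1), 13)
  expect_equal(sum(sp$test$y == 0), 35)
  expect_equal(sum(sp$test$y == 1), 6)
})

test_that("symmetric split and determinism", {
  fm <- toy_fm(10, 10)
  sp <- stratified_split(fm, test_fraction = 0.5, seed = 5)
  expect_equal(sum(sp$train$y == 0), 5)
  expect_equal(sum(sp$train$y == 1), 5)
  expect_equal(length(sp$test$y), 10)
  sp2 <- stratified_split(fm, test_fraction = 0.5, seed = 5)
  expect_identical(sp$train_idx, sp2$train_idx)
  sp3 <- stratified_split(fm, test_fraction = 0.5, seed = 6)
  expect_false(identical(sp$train_idx, sp3$train_idx))
  expect_error(stratified_split(toy_fm(10, 1)), "fewer than 2")
})

test_that("SMOTE balances 80/13 to 80/80 leaving majority rows bit-identical", {
  fm <- toy_fm(80, 13)
  out <- smote_oversample(fm, k_neighbors = 5, seed = 11)
  expect_equal(sum(out$y == 0), 80)
  expect_equal(sum(out$y == 1), 80)
  expect_identical(out$X[which(fm$y == 0), ], fm$X[which(fm$y == 0), ])
  # synthetic coordinates lie within the segment endpoints (convexity)
  synth <- out$X[-seq_len(nrow(fm$X)), , drop = FALSE]
  rngs <- apply(fm$X[fm$y == 1, ], 2, range)
  for (j in seq_len(ncol(synth))) {
    expect_true(all(synth[, j] >= rngs[1, j] - 1e-12 & synth[, j] <= rngs[2, j] + 1e-12))
  }
})

test_that("SMOTE interpolation formula and binary rounding rule", {
  fm <- toy_fm(3, 2, p = 2)
  fm$X[fm$y == 1, ] <- rbind(c(0, 0), c(1, 1))
  out <- smote_oversample(fm, k_neighbors = 1, seed = 2)
  synth <- out$X[-seq_len(5), , drop = FALSE]
  # with k = 1 the neighbour is the other minority point: x + u * (nn - x)
  # lies on the segment, and both coordinates are equal
  expect_equal(unname(synth[, 1]), unname(synth[, 2]))
  expect_true(all(synth >= 0 & synth <= 1))
  # binary-flagged columns are rounded half-up then clipped
  out_b <- smote_oversample(fm, k_neighbors = 1, seed = 2,
                            binary_columns = c("f1", "f2"))
  synth_b <- out_b$X[-seq_len(5), , drop = FALSE]
  expect_true(all(synth_b %in% c(0, 1)))
  expect_equal(unname(synth_b[, 1]), unname(floor(synth[, 1] + 0.5)))
})

test_that("SMOTE reduces k with a warning for tiny minorities", {
  fm <- toy_fm(10, 3)
  expect_warning(out <- smote_oversample(fm, k_neighbors = 5, seed = 1), "reduced")
  expect_equal(sum(out$y == 1), 10)
})

test_that("random undersampling matches the minority count without replacement", {
  fm <- toy_fm(80, 13)
  out <- random_undersample(fm, seed = 4)
  expect_equal(sum(out$y == 0), 13)
  expect_equal(sum(out$y == 1), 13)
  expect_equal(length(out$y), 26)
  # retained majority rows are original rows (no replacement: all distinct)
  expect_false(any(duplicated(out$X)))
  # already balanced input is unchanged up to row order
  bal <- toy_fm(7, 7)
  expect_equal(dim(random_undersample(bal, seed = 1)$X), dim(bal$X))
  # different seeds retain different majority subsets
  o1 <- random_undersample(fm, seed = 1); o2 <- random_undersample(fm, seed = 2)
  expect_false(identical(o1$X, o2$X))
})

test_that("one-hot encoding expands categoricals and preserves rows", {
  d <- generate_cohort(generative_risk_spec(n0 = 40, n1 = 8, seed = 3))
  fm <- encode_features(d)
  expect_equal(nrow(fm$X), 48)
  expect_true(all(c("artery_left", "artery_right") %in% colnames(fm$X)))
  expect_equal(unname(fm$X[, "artery_left"] + fm$X[, "artery_right"]), rep(1, 48))
  expect_setequal(unique(fm$meta$group), c("imaging", "simulation", "ecrf"))
  # all-numeric columns pass through unchanged
  expect_equal(unname(fm$X[, "pss"]), d$pss)
  d$bogus <- 1
  expect_error(encode_features(d), "unknown column")
})
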