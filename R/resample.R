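# Stratified data splitting and the two class-imbalance corrections: SMOTE
# oversampling of the minority class and random undersampling of the majority.

#' Stratified train/test split
#'
#' Per-class proportions are preserved; the training partition receives the
#' floor of the per-class train count, so fractional remainders go to the test
#' partition (115/19 at 70-30 gives train 80/13, test 35/6).
#'
#' @param fm a `feature_matrix`.
#' @param test_fraction fraction of each class assigned to the test set.
#' @param seed integer seed; the split is deterministic per seed.
#' @return list with `train`, `test` (feature matrices) and the index vectors
#'   `train_idx`, `test_idx`.
#' @export
stratified_split <- function(fm, test_fraction = 0.3, seed = 1) {
  validate_feature_matrix(fm)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop_module("risk_model", "test_fraction must lie in (0, 1)")
  }
  classes <- sort(unique(fm$y))
  if (length(classes) < 2) stop_module("risk_model", "both classes must be present")
  train_idx <- integer(0)
  with_local_seed(seed, {
    for (cl in classes) {
      idx <- which(fm$y == cl)
      if (length(idx) < 2) stop_module("risk_model", "class %d has fewer than 2 members", cl)
      n_train <- floor(length(idx) * (1 - test_fraction))
      train_idx <- c(train_idx, sample(idx, n_train))
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(fm$y), train_idx)
  list(train = fm_subset(fm, train_idx), test = fm_subset(fm, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' SMOTE oversampling of the minority class
#'
#' Synthesizes minority-class rows until both classes have equal counts. Each
#' synthetic row interpolates between a minority sample and one of its `k`
#' nearest minority neighbours: `x_new = x_i + u (x_nn - x_i)`,
#' `u ~ Uniform(0, 1)`. Binary-flagged columns are then rounded half-up and
#' clipped to {0, 1}. Majority rows are left untouched.
#'
#' @param fm training `feature_matrix`.
#' @param k_neighbors number of minority neighbours considered (reduced with a
#'   warning when the minority class is too small).
#' @param seed integer seed.
#' @param binary_columns names of columns to round/clip; defaults to the
#'   binary-flagged metadata columns.
#' @return a balanced `feature_matrix` (original rows first, then synthetic).
#' @export
smote_oversample <- function(fm, k_neighbors = 5, seed = 1,
                             binary_columns = fm$meta$name[fm$meta$binary]) {
  validate_feature_matrix(fm)
  if (k_neighbors < 1) stop_module("risk_model", "k_neighbors must be >= 1")
  n1 <- sum(fm$y == 1); n0 <- sum(fm$y == 0)
  minority <- if (n1 <= n0) 1L else 0L
  n_min <- min(n0, n1); n_maj <- max(n0, n1)
  if (n_min < 2) stop_module("risk_model", "minority class needs at least 2 members")
  if (n_min < k_neighbors + 1) {
    k_new <- n_min - 1
    warning(sprintf("[risk_model] k_neighbors reduced from %d to %d (minority size %d)",
                    k_neighbors, k_new, n_min))
    k_neighbors <- k_new
  }
  n_new <- n_maj - n_min
  if (n_new == 0) return(fm)
  Xm <- fm$X[fm$y == minority, , drop = FALSE]
  D <- as.matrix(stats::dist(Xm))
  diag(D) <- Inf
  nn <- t(apply(D, 1, function(dr) order(dr)[seq_len(k_neighbors)]))
  synth <- with_local_seed(seed, {
    base_i <- sample(seq_len(n_min), n_new, replace = TRUE)
    pick <- sample(seq_len(k_neighbors), n_new, replace = TRUE)
    u <- stats::runif(n_new)
    Xi <- Xm[base_i, , drop = FALSE]
    Xn <- Xm[nn[cbind(base_i, pick)], , drop = FALSE]
    Xi + u * (Xn - Xi)
  })
  bc <- intersect(binary_columns, colnames(synth))
  synth[, bc] <- pmin(pmax(floor(synth[, bc] + 0.5), 0), 1)  # round half-up, clip
  structure(list(X = rbind(fm$X, synth),
                 y = c(fm$y, rep(minority, n_new)),
                 meta = fm$meta), class = "feature_matrix")
}

#' Random undersampling of the majority class
#'
#' Subsamples the majority class without replacement down to the minority
#' count; minority rows are untouched. Row order of retained rows is
#' preserved.
#'
#' @param fm training `feature_matrix`.
#' @param seed integer seed.
#' @return a balanced `feature_matrix`.
#' @export
random_undersample <- function(fm, seed = 1) {
  validate_feature_matrix(fm)
  n1 <- sum(fm$y == 1); n0 <- sum(fm$y == 0)
  minority <- if (n1 <= n0) 1L else 0L
  n_min <- min(n0, n1)
  maj_idx <- which(fm$y != minority)
  keep <- with_local_seed(seed, sort(sample(maj_idx, n_min)))
  fm_subset(fm, sort(c(which(fm$y == minority), keep)))
}

# stratified fold assignment: per-class shuffle, round-robin folds
stratified_folds <- function(y, n_folds, seed) {
  fold <- integer(length(y))
  with_local_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}
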