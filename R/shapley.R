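# Shapley-value feature attribution for the fitted classifier, on the
# log-odds (margin) scale: exact subset enumeration for small feature counts,
# a permutation-sampling estimator for larger ones, and the global
# mean-|value| importance ranking. Absent features are marginalized
# interventionally: model output is averaged over a fixed background sample.

model_margin_fun <- function(model) {
  if (inherits(model, "gbt_model")) {
    function(X) gbt_margin(model, X)
  } else if (is.function(model)) {
    model
  } else {
    stop_module("attribution", "model must be a gbt_model or a function(X) -> margin")
  }
}

as_matrix_X <- function(X) {
  if (inherits(X, "feature_matrix")) X$X else as.matrix(X)
}

new_attribution_set <- function(values, baseline, margins, feature_names, se = NULL,
                                check_tol = NULL) {
  colnames(values) <- feature_names
  imp <- colMeans(abs(values))
  ranking <- feature_names[order(-imp, feature_names)]
  att <- structure(list(values = values, baseline = baseline, margins = margins,
                        global_importance = imp, ranking = ranking, se = se),
                   class = "attribution_set")
  if (!is.null(check_tol)) {
    gap <- max(abs(rowSums(values) - (margins - baseline)))
    if (gap > check_tol) {
      stop_module("attribution", "local accuracy violated: residual %.2e > %.2e", gap, check_tol)
    }
  }
  att
}

#' @export
print.attribution_set <- function(x, ...) {
  cat(sprintf("<attribution_set> %d samples x %d features, baseline %.4f\n",
              nrow(x$values), ncol(x$values), x$baseline))
  top <- utils::head(x$ranking, 5)
  cat("  top features:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' Exact Shapley attributions by subset enumeration
#'
#' Classic Shapley values over all feature subsets; feasible for encoded
#' feature counts up to 15 (2^p subset evaluations). Attributions are on the
#' model's log-odds scale and satisfy the efficiency axiom: per sample they
#' sum to `F(x) - baseline`, with the baseline the mean margin over the
#' background sample.
#'
#' @param model a `gbt_model` or a `function(X) -> margin`.
#' @param X rows to explain (`feature_matrix` or matrix).
#' @param background background sample used to marginalize absent features
#'   (matrix; capped at 100 rows).
#' @return an `attribution_set`.
#' @export
exact_shapley <- function(model, X, background) {
  f <- model_margin_fun(model)
  X <- as_matrix_X(X); background <- as_matrix_X(background)
  p <- ncol(X)
  if (p > 15) {
    stop_module("attribution", "exact enumeration limited to 15 features (got %d); use sampled_shapley", p)
  }
  if (nrow(background) > 100) background <- background[seq_len(100), , drop = FALSE]
  ne <- nrow(X); nb <- nrow(background)
  nsub <- bitwShiftL(1L, p)
  # v[s+1, i]: mean model output with subset s of features taken from x_i
  v <- matrix(0, nsub, ne)
  bg_rep <- background[rep(seq_len(nb), ne), , drop = FALSE]
  row_of <- rep(seq_len(ne), each = nb)
  for (s in 0:(nsub - 1L)) {
    H <- bg_rep
    for (j in seq_len(p)) {
      if (bitwAnd(s, bitwShiftL(1L, j - 1L))) H[, j] <- X[row_of, j]
    }
    v[s + 1L, ] <- rowsum(f(H), row_of)[, 1] / nb
  }
  fact <- factorial(0:p)
  values <- matrix(0, ne, p)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    subsets <- which(bitwAnd(0:(nsub - 1L), bit) == 0L) - 1L
    sizes <- vapply(subsets, function(s) sum(bitwAnd(s, bitwShiftL(1L, 0:(p - 1L))) != 0), numeric(1))
    w <- fact[sizes + 1] * fact[p - sizes] / fact[p + 1]
    for (k in seq_along(subsets)) {
      s <- subsets[k]
      values[, j] <- values[, j] + w[k] * (v[s + bit + 1L, ] - v[s + 1L, ])
    }
  }
  new_attribution_set(values, baseline = mean(f(background)), margins = f(X),
                      feature_names = colnames(X), check_tol = 1e-8)
}

#' Permutation-sampling Shapley estimator
#'
#' Monte-Carlo estimate of the Shapley values: for each sampled feature
#' permutation, features are revealed in order and the marginal change in the
#' background-averaged model output is credited to the revealed feature. The
#' estimator is unbiased for the exact value; per-feature standard errors are
#' reported from the across-permutation spread.
#'
#' @inheritParams exact_shapley
#' @param n_permutations number of sampled permutations (>= 10).
#' @param seed integer seed; the estimate is deterministic per seed.
#' @return an `attribution_set` with standard errors in `se`.
#' @export
sampled_shapley <- function(model, X, background, n_permutations = 200, seed = 1) {
  if (n_permutations < 10) stop_module("attribution", "n_permutations must be >= 10")
  f <- model_margin_fun(model)
  X <- as_matrix_X(X); background <- as_matrix_X(background)
  if (nrow(background) > 100) background <- background[seq_len(100), , drop = FALSE]
  p <- ncol(X); ne <- nrow(X); nb <- nrow(background)
  bg_rep <- background[rep(seq_len(nb), ne), , drop = FALSE]
  row_of <- rep(seq_len(ne), each = nb)
  baseline_vec <- rowsum(f(bg_rep), row_of)[, 1] / nb
  acc <- matrix(0, ne, p)
  acc2 <- matrix(0, ne, p)
  with_local_seed(seed, {
    for (it in seq_len(n_permutations)) {
      perm <- sample.int(p)
      H <- bg_rep
      prev <- baseline_vec
      for (j in perm) {
        H[, j] <- X[row_of, j]
        cur <- rowsum(f(H), row_of)[, 1] / nb
        acc[, j] <- acc[, j] + (cur - prev)
        acc2[, j] <- acc2[, j] + (cur - prev)^2
        prev <- cur
      }
    }
  })
  values <- acc / n_permutations
  se <- sqrt(pmax(acc2 / n_permutations - values^2, 0) / n_permutations)
  colnames(se) <- colnames(X)
  new_attribution_set(values, baseline = mean(baseline_vec), margins = f(X),
                      feature_names = colnames(X), se = se)
}

#' Global feature importance from an attribution set
#'
#' Mean absolute Shapley value per feature, sorted descending (ties broken
#' lexicographically by feature name).
#'
#' @param att an `attribution_set`.
#' @return data.frame with `feature`, `mean_abs_shap`, `rank`.
#' @export
global_importance <- function(att) {
  stopifnot(inherits(att, "attribution_set"))
  imp <- att$global_importance
  o <- order(-imp, names(imp))
  data.frame(feature = names(imp)[o], mean_abs_shap = unname(imp[o]),
             rank = seq_along(imp))
}

#' Write a global importance table as CSV
#' @param att an `attribution_set`.
#' @param path CSV path.
#' @export
write_importance_csv <- function(att, path) {
  utils::write.csv(global_importance(att), path, row.names = FALSE)
  invisible(path)
}

#' Horizontal-bar plot of global feature importance
#' @param att an `attribution_set`.
#' @param top_n number of features shown.
#' @param ... passed to [graphics::barplot()].
#' @export
plot_importance <- function(att, top_n = 12, ...) {
  gi <- utils::head(global_importance(att), top_n)
  op <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(gi$mean_abs_shap), names.arg = rev(gi$feature), horiz = TRUE,
                    las = 1, xlab = "mean |Shapley value| (log-odds)",
                    main = "Global feature importance", ...)
  invisible(gi)
}
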