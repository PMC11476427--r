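# Gradient-boosted trees for binary classification, implemented from first
# principles: logarithmic loss, base score at the training log-odds,
# pseudo-residuals r = y - sigmoid(F), depth-limited regression trees fit to
# the residuals with Friedman's mean-squared-error improvement score, leaf
# values refined by one Newton step, and a shrinkage (learning-rate) update.

# fit a regression tree to residuals r with Newton denominators den; returns
# flat arrays (feature, threshold, left, right, value, is_leaf)
fit_reg_tree <- function(X, r, den, max_depth, min_leaf = 1) {
  feature <- integer(0); threshold <- numeric(0)
  left <- integer(0); right <- integer(0)
  value <- numeric(0); is_leaf <- logical(0)
  new_node <- function() {
    feature[length(feature) + 1L] <<- NA_integer_
    threshold[length(threshold) + 1L] <<- NA_real_
    left[length(left) + 1L] <<- NA_integer_
    right[length(right) + 1L] <<- NA_integer_
    value[length(value) + 1L] <<- NA_real_
    is_leaf[length(is_leaf) + 1L] <<- TRUE
    length(feature)
  }
  best_split <- function(idx) {
    n <- length(idx)
    if (n < 2 * min_leaf) return(NULL)
    rsub <- r[idx]
    if (max(rsub) - min(rsub) < 1e-15) return(NULL)
    best <- NULL; best_imp <- 0
    for (f in seq_len(ncol(X))) {
      xv <- X[idx, f]
      o <- order(xv)
      xs <- xv[o]; rs <- rsub[o]
      csum <- cumsum(rs)
      tot <- csum[n]
      nl <- seq_len(n - 1)
      valid <- xs[-n] != xs[-1] & nl >= min_leaf & (n - nl) >= min_leaf
      if (!any(valid)) next
      ml <- csum[-n] / nl
      mr <- (tot - csum[-n]) / (n - nl)
      imp <- nl * (n - nl) / n * (ml - mr)^2
      imp[!valid] <- -Inf
      k <- which.max(imp)
      if (imp[k] > best_imp + 1e-15) {
        best_imp <- imp[k]
        best <- list(feature = f, threshold = (xs[k] + xs[k + 1]) / 2,
                     left_idx = idx[o[seq_len(k)]], right_idx = idx[o[(k + 1):n]])
      }
    }
    best
  }
  leaf_value <- function(idx) sum(r[idx]) / (sum(den[idx]) + 1e-12)
  grow <- function(idx, depth) {
    id <- new_node()
    sp <- if (depth < max_depth) best_split(idx) else NULL
    if (is.null(sp)) {
      value[id] <<- leaf_value(idx)
    } else {
      feature[id] <<- sp$feature
      threshold[id] <<- sp$threshold
      is_leaf[id] <<- FALSE
      left[id] <<- grow(sp$left_idx, depth + 1)
      right[id] <<- grow(sp$right_idx, depth + 1)
    }
    id
  }
  grow(seq_len(nrow(X)), 0)
  list(feature = feature, threshold = threshold, left = left, right = right,
       value = value, is_leaf = is_leaf)
}

predict_tree <- function(tree, X) {
  n <- nrow(X)
  node <- rep(1L, n)
  repeat {
    lf <- tree$is_leaf[node]
    if (all(lf)) break
    act <- which(!lf)
    nd <- node[act]
    goleft <- X[cbind(act, tree$feature[nd])] <= tree$threshold[nd]
    node[act] <- ifelse(goleft, tree$left[nd], tree$right[nd])
  }
  tree$value[node]
}

#' Fit a gradient-boosted-tree binary classifier
#'
#' Stagewise additive model under logarithmic loss: the base score is the
#' log-odds of the training prevalence; each stage fits a depth-limited
#' regression tree to the pseudo-residuals `y - sigmoid(F)` using Friedman's
#' MSE improvement for split selection, refines leaf values with one Newton
#' step (toggleable to the plain least-squares leaf mean), and adds the tree
#' scaled by the learning rate.
#'
#' @param fm training `feature_matrix` (or a list with `X`, `y`).
#' @param n_estimators number of boosting stages; default 100.
#' @param learning_rate shrinkage per stage; default 0.1.
#' @param max_depth maximum regression-tree depth; default 3.
#' @param seed unused (the fit is deterministic); kept for interface symmetry.
#' @param newton_leaves refine leaf values by a Newton step (default TRUE).
#' @return an object of class `gbt_model`.
#' @export
gbt_fit <- function(fm, n_estimators = 100, learning_rate = 0.1, max_depth = 3,
                    seed = NULL, newton_leaves = TRUE) {
  X <- fm$X; y <- fm$y
  if (length(unique(y)) < 2) stop_module("risk_model", "training set must contain both classes")
  prev <- mean(y)
  f0 <- stats::qlogis(prev)
  Fm <- rep(f0, length(y))
  trees <- vector("list", n_estimators)
  train_loss <- numeric(n_estimators)
  for (m in seq_len(n_estimators)) {
    p <- stats::plogis(Fm)
    r <- y - p
    den <- if (newton_leaves) p * (1 - p) else rep(1, length(y))
    tree <- fit_reg_tree(X, r, den, max_depth)
    Fm <- Fm + learning_rate * predict_tree(tree, X)
    trees[[m]] <- tree
    pm <- stats::plogis(Fm)
    train_loss[m] <- -mean(y * log(pmax(pm, 1e-15)) + (1 - y) * log(pmax(1 - pm, 1e-15)))
  }
  structure(list(f0 = f0, trees = trees, learning_rate = learning_rate,
                 n_estimators = n_estimators, max_depth = max_depth,
                 feature_names = colnames(X), train_loss = train_loss,
                 loss = "log_loss", newton_leaves = newton_leaves),
            class = "gbt_model")
}

#' @export
print.gbt_model <- function(x, ...) {
  cat(sprintf("<gbt_model> %d trees (depth <= %d, lr %.3g), F0 = %.4f, final train log-loss %.4f\n",
              x$n_estimators, x$max_depth, x$learning_rate, x$f0,
              x$train_loss[length(x$train_loss)]))
  invisible(x)
}

# raw margin F_M(x) = F0 + lr * sum_m h_m(x)
gbt_margin <- function(model, X) {
  if (!is.null(model$feature_names)) {
    if (is.null(colnames(X)) || !identical(colnames(X), model$feature_names)) {
      if (!is.null(colnames(X)) && setequal(colnames(X), model$feature_names)) {
        X <- X[, model$feature_names, drop = FALSE]
      } else {
        stop_module("risk_model", "feature columns do not match the training metadata")
      }
    }
  }
  out <- rep(model$f0, nrow(X))
  for (tree in model$trees) out <- out + model$learning_rate * predict_tree(tree, X)
  out
}

#' Predict event probability and class from a fitted GBT model
#'
#' The event risk score is `sigmoid(F_M(x))`, the composition of the base
#' score with all weak-learner contributions.
#'
#' @param model a `gbt_model`.
#' @param newdata a `feature_matrix` or numeric matrix with matching columns.
#' @param threshold decision threshold on the probability; default 0.5.
#' @return data.frame with `margin`, `prob`, `class`.
#' @export
gbt_predict <- function(model, newdata, threshold = 0.5) {
  X <- if (inherits(newdata, "feature_matrix")) newdata$X else as.matrix(newdata)
  mar <- gbt_margin(model, X)
  prob <- stats::plogis(mar)
  data.frame(margin = mar, prob = prob, class = as.integer(prob >= threshold))
}

#' Serialize / restore a GBT model as JSON
#' @param model a `gbt_model`.
#' @param path JSON file path.
#' @export
write_gbt_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_gbt_json
#' @export
read_gbt_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  obj$trees <- lapply(obj$trees, function(tr) {
    list(feature = as.integer(tr$feature), threshold = as.numeric(tr$threshold),
         left = as.integer(tr$left), right = as.integer(tr$right),
         value = as.numeric(tr$value), is_leaf = as.logical(tr$is_leaf))
  })
  structure(obj, class = "gbt_model")
}
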