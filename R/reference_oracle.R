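# Cross-check of the from-scratch gradient-boosting implementation against
# scikit-learn's GradientBoostingClassifier (run through the system python).
# The reference is used only as an independent oracle in tests and in the
# acceptance script; it never stands in for the package's own implementation.

#' Compare the package GBT against scikit-learn on synthetic datasets
#'
#' Generates logistic-ground-truth datasets, fits the package's
#' gradient-boosted trees and scikit-learn's `GradientBoostingClassifier`
#' with identical hyperparameters on each, and reports both test AUCs and the
#' median absolute difference of the predicted probabilities.
#'
#' @param n_datasets number of synthetic datasets.
#' @param n_train,n_test rows per partition.
#' @param p number of features.
#' @param seed0 base seed; dataset k uses `seed0 + k`.
#' @param n_estimators,learning_rate,max_depth shared GBT hyperparameters.
#' @param python python executable used for the reference fit.
#' @return data.frame with columns `dataset`, `auc_ours`, `auc_ref`,
#'   `prob_median_absdiff`.
#' @export
sklearn_gbt_oracle <- function(n_datasets = 10, n_train = 150, n_test = 250, p = 8,
                               seed0 = 100, n_estimators = 100, learning_rate = 0.1,
                               max_depth = 3, python = "python") {
  dir <- tempfile("gbt_oracle_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  manifest <- list()
  ours <- list()
  for (k in seq_len(n_datasets)) {
    d <- with_local_seed(seed0 + k, {
      beta <- c(1.2, -0.9, 0.7, -0.5, rep(0.25, max(0, p - 4)))[seq_len(p)]
      X <- matrix(stats::rnorm((n_train + n_test) * p), ncol = p,
                  dimnames = list(NULL, paste0("x", seq_len(p))))
      y <- stats::rbinom(n_train + n_test, 1, stats::plogis(X %*% beta))
      list(X = X, y = y)
    })
    tr <- seq_len(n_train)
    fm_tr <- structure(list(X = d$X[tr, , drop = FALSE], y = as.integer(d$y[tr]),
                            meta = data.frame(name = colnames(d$X), source = colnames(d$X),
                                              group = "ecrf", binary = FALSE)),
                       class = "feature_matrix")
    fm_te <- structure(list(X = d$X[-tr, , drop = FALSE], y = as.integer(d$y[-tr]),
                            meta = fm_tr$meta), class = "feature_matrix")
    model <- gbt_fit(fm_tr, n_estimators = n_estimators,
                     learning_rate = learning_rate, max_depth = max_depth)
    pr <- gbt_predict(model, fm_te)
    ours[[k]] <- list(auc = auc_trapezoid(pr$prob, fm_te$y), prob = pr$prob)
    trp <- file.path(dir, sprintf("train%02d.csv", k))
    tep <- file.path(dir, sprintf("test%02d.csv", k))
    utils::write.csv(data.frame(d$X[tr, ], y = d$y[tr]), trp, row.names = FALSE)
    utils::write.csv(data.frame(d$X[-tr, ], y = d$y[-tr]), tep, row.names = FALSE)
    manifest[[k]] <- list(train = trp, test = tep)
  }
  man_path <- file.path(dir, "manifest.json")
  out_path <- file.path(dir, "ref.json")
  jsonlite::write_json(list(datasets = manifest, out = out_path,
                            n_estimators = n_estimators, learning_rate = learning_rate,
                            max_depth = max_depth),
                       man_path, auto_unbox = TRUE, digits = NA)
  script <- file.path(dir, "ref_gbt.py")
  writeLines(c(
    "import json, sys",
    "import pandas as pd",
    "from sklearn.ensemble import GradientBoostingClassifier",
    "from sklearn.metrics import roc_auc_score",
    "cfg = json.load(open(sys.argv[1]))",
    "aucs, probs = [], []",
    "for ds in cfg['datasets']:",
    "    tr = pd.read_csv(ds['train']); te = pd.read_csv(ds['test'])",
    "    Xtr, ytr = tr.drop(columns='y'), tr['y']",
    "    Xte, yte = te.drop(columns='y'), te['y']",
    "    clf = GradientBoostingClassifier(n_estimators=cfg['n_estimators'],",
    "        learning_rate=cfg['learning_rate'], max_depth=cfg['max_depth'],",
    "        random_state=0)",
    "    clf.fit(Xtr, ytr)",
    "    pr = clf.predict_proba(Xte)[:, 1]",
    "    aucs.append(float(roc_auc_score(yte, pr)))",
    "    probs.append([float(v) for v in pr])",
    "json.dump({'auc': aucs, 'prob': probs}, open(cfg['out'], 'w'))"
  ), script)
  status <- system2(python, c(script, man_path), stdout = TRUE, stderr = TRUE)
  if (!file.exists(out_path)) {
    stop_module("risk_model", "reference oracle failed: %s", paste(status, collapse = "\n"))
  }
  ref <- jsonlite::read_json(out_path, simplifyVector = TRUE)
  data.frame(
    dataset = seq_len(n_datasets),
    auc_ours = vapply(ours, `[[`, numeric(1), "auc"),
    auc_ref = as.numeric(ref$auc),
    prob_median_absdiff = vapply(seq_len(n_datasets), function(k) {
      pref <- if (is.matrix(ref$prob)) ref$prob[k, ] else as.numeric(ref$prob[[k]])
      stats::median(abs(ours[[k]]$prob - pref))
    }, numeric(1))
  )
}
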