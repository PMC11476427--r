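# Feature encoding: cohort table -> numeric design matrix with one-hot
# expansion of categorical columns and per-column metadata.

#' Encode a cohort table into a numeric feature matrix
#'
#' Categorical (character or factor) columns are expanded into one indicator
#' column per level (full encoding, no reference level dropped); numeric
#' columns pass through. Column metadata records the feature group
#' (imaging / simulation / ecrf) and whether a column is binary, which the
#' SMOTE rounding rule needs.
#'
#' @param cohort a `cohort_table` (or data.frame with the same schema plus
#'   `event`).
#' @return an object of class `feature_matrix` with elements `X` (numeric
#'   matrix), `y` (0/1 labels) and `meta` (data.frame: name, source, group,
#'   binary).
#' @export
encode_features <- function(cohort) {
  d <- as.data.frame(cohort)
  groups <- attr(cohort, "groups") %||% cohort_feature_groups()
  feats <- unlist(groups, use.names = FALSE)
  known <- c(feats, "event")
  unknown <- setdiff(names(d), known)
  if (length(unknown)) stop_module("risk_model", "unknown column(s): %s", paste(unknown, collapse = ", "))
  miss <- setdiff(known, names(d))
  if (length(miss)) stop_module("risk_model", "missing column(s): %s", paste(miss, collapse = ", "))
  group_of <- function(nm) names(groups)[vapply(groups, function(g) nm %in% g, logical(1))][1]
  cols <- list(); meta <- list()
  for (nm in feats) {
    v <- d[[nm]]
    if (is.character(v) || is.factor(v)) {
      lev <- sort(unique(as.character(v)))
      for (lv in lev) {
        cn <- paste0(nm, "_", lv)
        cols[[cn]] <- as.numeric(as.character(v) == lv)
        meta[[cn]] <- data.frame(name = cn, source = nm, group = group_of(nm), binary = TRUE)
      }
    } else {
      if (anyNA(v)) stop_module("risk_model", "missing values in column %s", nm)
      cols[[nm]] <- as.numeric(v)
      meta[[nm]] <- data.frame(name = nm, source = nm, group = group_of(nm),
                               binary = all(v %in% c(0, 1)))
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  fm <- structure(list(X = X, y = as.integer(d$event),
                       meta = do.call(rbind, meta)), class = "feature_matrix")
  rownames(fm$meta) <- NULL
  validate_feature_matrix(fm)
  fm
}

validate_feature_matrix <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (anyNA(fm$X)) stop_module("risk_model", "feature matrix contains missing values")
  if (nrow(fm$X) != length(fm$y)) stop_module("risk_model", "row count does not match label count")
  if (!all(fm$y %in% c(0L, 1L))) stop_module("risk_model", "labels must be binary 0/1")
  bin <- fm$meta$name[fm$meta$binary]
  for (nm in bin) {
    if (!all(fm$X[, nm] %in% c(0, 1))) stop_module("risk_model", "binary column %s is not 0/1", nm)
  }
  invisible(fm)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d subjects x %d features (%d event), groups: %s\n",
              nrow(x$X), ncol(x$X), sum(x$y),
              paste(sprintf("%s=%d", names(table(x$meta$group)), table(x$meta$group)),
                    collapse = ", ")))
  invisible(x)
}

# subset helper preserving metadata
fm_subset <- function(fm, idx) {
  structure(list(X = fm$X[idx, , drop = FALSE], y = fm$y[idx], meta = fm$meta),
            class = "feature_matrix")
}
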