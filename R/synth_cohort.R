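# Synthetic patient cohorts with the event-prediction feature schema and a
# known logistic generative risk model, so that feature-importance recovery
# can be tested against the ground truth.
#
# Feature marginals are drawn from ranges consistent with the study
# demographics (e.g. hypertension prevalence 0.83, smoking 0.70, BMI
# 26.5 +/- 3.4) and with physiologic ranges of the simulation-derived
# quantities; class imbalance defaults to 115 event-free vs 19 event cases.

cohort_feature_groups <- function() {
  list(
    imaging = c("artery", "psv", "ica_stenosis_pct", "eca_stenosis_pct",
                "mean_arterial_pressure"),
    simulation = c("peak_tawss", "p_eca_over_cca", "p_ica_over_cca",
                   "vessel_avg_tawss", "vessel_avg_osi", "norm_area_low_tawss",
                   "norm_area_high_osi", "pss"),
    ecrf = c("smoking", "diabetes", "hypertension", "bmi", "alcohol_abuse", "statins")
  )
}

cohort_binary_columns <- function() {
  c("smoking", "diabetes", "hypertension", "alcohol_abuse", "statins")
}

# fixed reference scales used to standardize features inside the generative
# risk model (so effect sizes are in per-SD log-odds units)
cohort_reference_scales <- function() {
  data.frame(
    feature = c("psv", "ica_stenosis_pct", "eca_stenosis_pct", "mean_arterial_pressure",
                "peak_tawss", "p_eca_over_cca", "p_ica_over_cca", "vessel_avg_tawss",
                "vessel_avg_osi", "norm_area_low_tawss", "norm_area_high_osi", "pss",
                "bmi", "smoking", "diabetes", "hypertension", "alcohol_abuse", "statins"),
    mean = c(1.55, 72.5, 22.5, 100, 17, 0.95, 0.94, 2.6, 0.055, 0.2, 0.115, 66,
             26.48, 0.70, 0.35, 0.83, 0.10, 0.60),
    sd = c(0.55, 10.1, 10.7, 12, 9, 0.022, 0.027, 1.35, 0.045, 0.14, 0.09, 31,
           3.4, 0.46, 0.48, 0.38, 0.30, 0.49)
  )
}

#' Specification of the generative logistic risk model
#'
#' @param effects named numeric vector of per-feature effect sizes in log-odds
#'   units per standardized feature unit; names must be cohort feature columns.
#' @param intercept intercept of the logistic model (log-odds).
#' @param noise standard deviation of additive latent noise on the log-odds.
#' @param n0,n1 target class counts (no-event / event). Defaults 115 / 19.
#' @param seed integer seed.
#' @return an object of class `generative_risk_spec`.
#' @export
generative_risk_spec <- function(effects = default_risk_effects(),
                                 intercept = stats::qlogis(19 / 134),
                                 noise = 0, n0 = 115, n1 = 19, seed = 1) {
  feats <- unlist(cohort_feature_groups(), use.names = FALSE)
  bad <- setdiff(names(effects), setdiff(feats, "artery"))
  if (length(bad)) stop_module("synth_data", "unknown effect feature(s): %s", paste(bad, collapse = ", "))
  if (n0 < 1 || n1 < 1) stop_module("synth_data", "n0 and n1 must be >= 1")
  structure(list(effects = effects, intercept = intercept, noise = noise,
                 n0 = as.integer(n0), n1 = as.integer(n1), seed = as.integer(seed)),
            class = "generative_risk_spec")
}

#' Default generative effect sizes
#'
#' Plaque structural stress carries the largest effect, emulating a population
#' in which the biomechanical marker dominates event risk; the remaining
#' effects are moderate clinical and hemodynamic contributions.
#' @return named numeric vector of log-odds effects.
#' @export
default_risk_effects <- function() {
  c(pss = 1.1, norm_area_high_osi = 0.6, vessel_avg_tawss = -0.45,
    ica_stenosis_pct = 0.5, hypertension = 0.45, smoking = 0.4, psv = 0.35,
    diabetes = 0.3, statins = -0.3, bmi = 0.2, alcohol_abuse = 0.15)
}

#' @export
print.generative_risk_spec <- function(x, ...) {
  cat(sprintf("<generative_risk_spec> %d effects, intercept %.3f, targets %d/%d, seed %d\n",
              length(x$effects), x$intercept, x$n0, x$n1, x$seed))
  invisible(x)
}

# draw n subjects with Bernoulli labels from the generative model (no
# rejection to exact counts); RNG state is the caller's responsibility
draw_cohort_rows <- function(spec, n) {
  rtrunc <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  d <- data.frame(
    artery = sample(c("left", "right"), n, replace = TRUE),
    psv = rtrunc(stats::rlnorm(n, log(1.5), 0.35), 0.3, 4),
    ica_stenosis_pct = 50 + 45 * stats::rbeta(n, 2, 2),
    eca_stenosis_pct = 60 * stats::rbeta(n, 1.5, 2.5),
    mean_arterial_pressure = rtrunc(stats::rnorm(n, 100, 12), 70, 140),
    peak_tawss = rtrunc(stats::rlnorm(n, log(15), 0.5), 1, 80),
    p_eca_over_cca = 0.9 + 0.1 * stats::rbeta(n, 2, 2),
    p_ica_over_cca = 0.88 + 0.12 * stats::rbeta(n, 2, 2),
    vessel_avg_tawss = rtrunc(stats::rlnorm(n, log(2.5), 0.5), 0.3, 12),
    vessel_avg_osi = 0.5 * stats::rbeta(n, 1.2, 9),
    norm_area_low_tawss = stats::rbeta(n, 1.5, 6),
    norm_area_high_osi = stats::rbeta(n, 1.2, 9),
    pss = rtrunc(stats::rlnorm(n, log(60), 0.45), 10, 250),
    smoking = stats::rbinom(n, 1, 0.70),
    diabetes = stats::rbinom(n, 1, 0.35),
    hypertension = stats::rbinom(n, 1, 0.83),
    bmi = rtrunc(stats::rnorm(n, 26.48, 3.4), 16, 45),
    alcohol_abuse = stats::rbinom(n, 1, 0.10),
    statins = stats::rbinom(n, 1, 0.60),
    stringsAsFactors = FALSE
  )
  sc <- cohort_reference_scales()
  eta <- rep(spec$intercept, n)
  for (nm in names(spec$effects)) {
    i <- match(nm, sc$feature)
    z <- (d[[nm]] - sc$mean[i]) / sc$sd[i]
    eta <- eta + spec$effects[[nm]] * z
  }
  if (spec$noise > 0) eta <- eta + stats::rnorm(n, 0, spec$noise)
  p <- stats::plogis(eta)
  d$event <- stats::rbinom(n, 1, p)
  attr(d, "latent_prob") <- p
  d
}

#' Draw cohort rows without rejection sampling
#'
#' Labels are Bernoulli draws from the logistic ground truth; class counts are
#' random. Useful for checking prevalence convergence.
#'
#' @param spec a `generative_risk_spec`.
#' @param n number of subjects.
#' @param seed optional seed overriding `spec$seed`.
#' @return a data.frame with the cohort schema and an `event` column.
#' @export
sample_cohort_rows <- function(spec, n, seed = spec$seed) {
  with_local_seed(seed, draw_cohort_rows(spec, n))
}

#' Generate an imbalanced cohort with exact class counts
#'
#' Rejection-samples subjects from the generative logistic risk model until
#' exactly `n0` event-free and `n1` event rows are collected (default 115/19).
#'
#' @param spec a `generative_risk_spec`.
#' @return a `cohort_table` data.frame with the event-prediction feature
#'   schema plus the binary `event` label.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "generative_risk_spec"))
  with_local_seed(spec$seed, {
    need0 <- spec$n0; need1 <- spec$n1
    got0 <- NULL; got1 <- NULL
    for (batch in seq_len(200)) {
      d <- draw_cohort_rows(spec, 2L * (need0 + need1))
      attr(d, "latent_prob") <- NULL
      d0 <- d[d$event == 0, , drop = FALSE]
      d1 <- d[d$event == 1, , drop = FALSE]
      got0 <- rbind(got0, d0)[seq_len(min(need0, nrow(d0) + NROW(got0))), , drop = FALSE]
      got1 <- rbind(got1, d1)[seq_len(min(need1, nrow(d1) + NROW(got1))), , drop = FALSE]
      if (NROW(got0) >= need0 && NROW(got1) >= need1) break
    }
    if (NROW(got0) < need0 || NROW(got1) < need1) {
      stop_module("synth_data",
                  "infeasible effect sizes: could not reach class counts %d/%d after bounded retries",
                  need0, need1)
    }
    out <- rbind(got0, got1)
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("cohort_table", "data.frame")
    attr(out, "groups") <- cohort_feature_groups()
    attr(out, "spec") <- spec
    validate_cohort_table(out)
    out
  })
}

#' Validate a cohort table against its schema invariants
#' @param d a `cohort_table` (or compatible data.frame).
#' @return the table, invisibly.
#' @export
validate_cohort_table <- function(d) {
  feats <- unlist(cohort_feature_groups(), use.names = FALSE)
  miss <- setdiff(c(feats, "event"), names(d))
  if (length(miss)) stop_module("synth_data", "cohort missing column(s): %s", paste(miss, collapse = ", "))
  for (nm in c(cohort_binary_columns(), "event")) {
    if (!all(d[[nm]] %in% c(0, 1))) stop_module("synth_data", "column %s must be binary 0/1", nm)
  }
  for (nm in c("norm_area_low_tawss", "norm_area_high_osi")) {
    if (any(d[[nm]] < 0 | d[[nm]] > 1)) stop_module("synth_data", "column %s must lie in [0, 1]", nm)
  }
  if (any(d$vessel_avg_osi < 0 | d$vessel_avg_osi > 0.5)) {
    stop_module("synth_data", "vessel_avg_osi must lie in [0, 0.5]")
  }
  for (nm in c("psv", "pss", "peak_tawss", "vessel_avg_tawss", "bmi", "mean_arterial_pressure")) {
    if (any(d[[nm]] <= 0)) stop_module("synth_data", "column %s must be positive", nm)
  }
  if (!all(d$artery %in% c("left", "right"))) stop_module("synth_data", "artery must be left/right")
  invisible(d)
}

#' Write / read a generative risk specification as JSON
#' @param spec a `generative_risk_spec`.
#' @param path JSON path.
#' @export
write_risk_spec_json <- function(spec, path) {
  jsonlite::write_json(list(effects = as.list(spec$effects), intercept = spec$intercept,
                            noise = spec$noise, n0 = spec$n0, n1 = spec$n1,
                            seed = spec$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_risk_spec_json
#' @export
read_risk_spec_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  generative_risk_spec(effects = unlist(o$effects), intercept = o$intercept,
                       noise = o$noise, n0 = o$n0, n1 = o$n1, seed = o$seed)
}

#' Write / read a cohort table as CSV
#' @param d a `cohort_table`.
#' @param path CSV path.
#' @export
write_cohort_csv <- function(d, path) {
  utils::write.csv(as.data.frame(d), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(d) <- c("cohort_table", "data.frame")
  attr(d, "groups") <- cohort_feature_groups()
  validate_cohort_table(d)
  d
}
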