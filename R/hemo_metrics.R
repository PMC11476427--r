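# Hemodynamic wall metrics: TAWSS, OSI and the simulation-based feature set
# (peak / vessel-average shear, low-shear and high-oscillation wall fractions,
# boundary pressure ratios).

#' Wall shear stress record
#'
#' Time-resolved signed scalar wall shear stress along the wall, sampled at
#' ordered wall points with an arc-length coordinate. The sign convention is
#' positive for streamwise-forward shear.
#'
#' @param arclength strictly increasing arc-length coordinates (m).
#' @param tau matrix of wall shear stress (Pa), points x time samples.
#' @param times time samples spanning exactly one cardiac cycle `[0, T]`.
#' @param period cycle duration T (s).
#' @return an object of class `wall_shear_record`.
#' @export
wall_shear_record <- function(arclength, tau, times, period) {
  tau <- as.matrix(tau)
  if (any(diff(arclength) <= 0)) stop_module("hemo_metrics", "arclength must be strictly increasing")
  if (length(arclength) != nrow(tau)) stop_module("hemo_metrics", "arclength/tau size mismatch")
  if (length(times) != ncol(tau)) stop_module("hemo_metrics", "times/tau size mismatch")
  if (!all(is.finite(tau))) stop_module("hemo_metrics", "wall shear values must be finite")
  structure(list(arclength = arclength, tau = tau, times = times, period = period),
            class = "wall_shear_record")
}

#' @export
print.wall_shear_record <- function(x, ...) {
  cat(sprintf("<wall_shear_record> %d wall points, %d time samples, T=%.4g s\n",
              nrow(x$tau), ncol(x$tau), x$period))
  invisible(x)
}

check_cycle_grid <- function(record) {
  t <- record$times
  T <- record$period
  if (abs(t[1]) > 1e-9 * T || abs(t[length(t)] - T) > 1e-9 * T) {
    stop_module("hemo_metrics", "record must span exactly one cycle [0, T]")
  }
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-8 * mean(dt)) {
    stop_module("hemo_metrics", "record time samples must be uniformly spaced")
  }
  invisible(TRUE)
}

#' Time-averaged wall shear stress (TAWSS)
#'
#' Per-point time average of the wall shear stress magnitude over one cardiac
#' cycle, by trapezoidal quadrature:
#' `TAWSS = (1/T) * integral_0^T |tau_w| dt`.
#' The magnitude convention makes TAWSS non-negative, as required by the
#' 0.4 Pa low-shear threshold and by the oscillatory-shear-index denominator.
#'
#' @param record a `wall_shear_record` spanning exactly one cycle.
#' @return numeric vector of per-point TAWSS (Pa).
#' @export
tawss <- function(record) {
  stopifnot(inherits(record, "wall_shear_record"))
  check_cycle_grid(record)
  w <- trapz_weights(record$times)
  as.numeric(abs(record$tau) %*% w) / record$period
}

trapz_weights <- function(t) {
  n <- length(t)
  dt <- diff(t)
  w <- numeric(n)
  w[1] <- dt[1] / 2
  w[n] <- dt[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dt[-1] + dt[-(n - 1)]) / 2
  w
}

#' Oscillatory shear index (OSI)
#'
#' `OSI = 0.5 * (1 - |mean(tau_w)| / mean(|tau_w|))`, with both means taken
#' over one cycle by trapezoidal quadrature. OSI is 0 for wholly
#' unidirectional shear and 0.5 for zero-mean oscillatory shear. Wall points
#' with identically zero shear (`mean |tau_w| = 0`) are assigned OSI 0 — the
#' undefined 0/0 is resolved toward "no oscillation".
#'
#' @param record a `wall_shear_record` spanning exactly one cycle.
#' @return numeric vector of per-point OSI values in `[0, 0.5]`.
#' @export
osi <- function(record) {
  stopifnot(inherits(record, "wall_shear_record"))
  check_cycle_grid(record)
  w <- trapz_weights(record$times)
  num <- abs(as.numeric(record$tau %*% w))
  den <- as.numeric(abs(record$tau) %*% w)
  out <- ifelse(den > 0, 0.5 * (1 - num / den), 0)
  pmin(pmax(out, 0), 0.5)
}

#' Summarize wall fields and pressures into the simulation-based feature set
#'
#' Computes peak and arc-length-weighted vessel averages of TAWSS and OSI, the
#' normalized wall fractions with TAWSS below the atherogenic threshold and
#' OSI above the oscillation threshold, and the cycle-mean absolute pressure
#' ratios of the two outlets to the inlet. In the planar model "areas" are
#' wall-boundary-length fractions. The fraction of wall above the 40 Pa
#' high-shear threshold is computed as a diagnostic but is not part of the
#' feature set.
#'
#' @param tawss_field per-point TAWSS (Pa).
#' @param osi_field per-point OSI, on the same wall discretization.
#' @param wall_arclengths strictly increasing arc-length coordinates (m).
#' @param pressure_traces named list with numeric gauge-pressure traces (Pa)
#'   `cca`, `ica`, `eca`, sampled over one cycle.
#' @param thresholds list with `low_tawss` (Pa, default 0.4), `high_osi`
#'   (default 0.2) and `high_tawss` (Pa, default 40).
#' @param pressure_offset reference absolute-pressure offset added to gauge
#'   pressures before forming ratios (Pa). Default 80 mmHg.
#' @return an object of class `hemodynamic_features`.
#' @export
feature_summary <- function(tawss_field, osi_field, wall_arclengths, pressure_traces,
                            thresholds = list(low_tawss = 0.4, high_osi = 0.2, high_tawss = 40),
                            pressure_offset = 80 * 133.322) {
  n <- length(wall_arclengths)
  if (length(tawss_field) != n || length(osi_field) != n) {
    stop_module("hemo_metrics", "fields and wall arc-lengths have mismatched discretizations")
  }
  if (any(diff(wall_arclengths) <= 0)) stop_module("hemo_metrics", "wall arc-lengths must be increasing")
  # per-point weights: half the adjacent intervals (ends get half intervals)
  w <- trapz_weights(wall_arclengths)
  W <- sum(w)
  pmean <- function(tr) mean(tr) + pressure_offset
  p_cca <- pmean(pressure_traces$cca)
  p_ica <- pmean(pressure_traces$ica)
  p_eca <- pmean(pressure_traces$eca)
  feat <- list(
    peak_tawss = max(tawss_field),
    vessel_avg_tawss = sum(w * tawss_field) / W,
    vessel_avg_osi = sum(w * osi_field) / W,
    frac_low_tawss = sum(w[tawss_field < thresholds$low_tawss]) / W,
    frac_high_osi = sum(w[osi_field > thresholds$high_osi]) / W,
    p_eca_over_cca = p_eca / p_cca,
    p_ica_over_cca = p_ica / p_cca,
    diag_frac_high_tawss = sum(w[tawss_field > thresholds$high_tawss]) / W
  )
  out <- structure(feat, class = "hemodynamic_features")
  validate_hemodynamic_features(out)
  out
}

validate_hemodynamic_features <- function(f) {
  stopifnot(inherits(f, "hemodynamic_features"))
  tol <- 1e-9
  if (!(f$peak_tawss >= f$vessel_avg_tawss - tol && f$vessel_avg_tawss >= -tol)) {
    stop_module("hemo_metrics", "invariant violated: peak_tawss >= vessel_avg_tawss >= 0")
  }
  if (f$vessel_avg_osi < -tol || f$vessel_avg_osi > 0.5 + tol) {
    stop_module("hemo_metrics", "invariant violated: vessel_avg_osi in [0, 0.5]")
  }
  for (nm in c("frac_low_tawss", "frac_high_osi")) {
    if (f[[nm]] < -tol || f[[nm]] > 1 + tol) {
      stop_module("hemo_metrics", "invariant violated: %s in [0, 1]", nm)
    }
  }
  invisible(f)
}

#' @export
print.hemodynamic_features <- function(x, ...) {
  cat("<hemodynamic_features>\n")
  cat(sprintf("  peak TAWSS        %.4g Pa\n", x$peak_tawss))
  cat(sprintf("  vessel avg TAWSS  %.4g Pa\n", x$vessel_avg_tawss))
  cat(sprintf("  vessel avg OSI    %.4g\n", x$vessel_avg_osi))
  cat(sprintf("  frac low TAWSS    %.4g\n", x$frac_low_tawss))
  cat(sprintf("  frac high OSI     %.4g\n", x$frac_high_osi))
  cat(sprintf("  P_ECA/P_CCA       %.4g\n", x$p_eca_over_cca))
  cat(sprintf("  P_ICA/P_CCA       %.4g\n", x$p_ica_over_cca))
  invisible(x)
}

#' @export
as.data.frame.hemodynamic_features <- function(x, ...) {
  data.frame(peak_tawss = x$peak_tawss, vessel_avg_tawss = x$vessel_avg_tawss,
             vessel_avg_osi = x$vessel_avg_osi, frac_low_tawss = x$frac_low_tawss,
             frac_high_osi = x$frac_high_osi, p_eca_over_cca = x$p_eca_over_cca,
             p_ica_over_cca = x$p_ica_over_cca)
}

#' Write a wall shear record as CSV (arclength x time) with JSON metadata
#' @param record a `wall_shear_record`.
#' @param path CSV path; metadata goes to `<path>.json`.
#' @export
write_wall_shear_csv <- function(record, path) {
  m <- cbind(arclength = record$arclength, record$tau)
  colnames(m) <- c("arclength", sprintf("t%03d", seq_along(record$times) - 1L))
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  jsonlite::write_json(list(period = record$period, times = record$times),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}
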