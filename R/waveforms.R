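# Boundary-condition construction: cardiac-cycle waveforms built from the two
# Doppler ultrasound landmarks (PSV, EDV) and the pulse rate, and their
# conversion to mass-flow and inflow velocity profiles.

#' Blood fluid properties
#'
#' Newtonian blood model: density 1050 kg/m^3, dynamic viscosity 0.0035 Pa s.
#'
#' @param density blood density in kg/m^3.
#' @param viscosity dynamic viscosity in Pa s.
#' @return an object of class `fluid_props`.
#' @export
fluid_props <- function(density = 1050, viscosity = 0.0035) {
  if (!is.numeric(density) || density <= 0 || !is.numeric(viscosity) || viscosity <= 0) {
    stop_module("boundary_conditions", "density and viscosity must be strictly positive")
  }
  structure(list(density = density, viscosity = viscosity), class = "fluid_props")
}

#' Cardiac cycle duration from pulse rate
#'
#' @param pulse_rate heart rate in beats per minute, within `[30, 200]`.
#' @return cycle duration in seconds, `60 / pulse_rate`.
#' @export
cycle_duration <- function(pulse_rate) {
  if (!is.numeric(pulse_rate) || length(pulse_rate) != 1L || !is.finite(pulse_rate) ||
      pulse_rate < 30 || pulse_rate > 200) {
    stop_module("boundary_conditions", "pulse_rate must lie in [30, 200] beats/min")
  }
  60 / pulse_rate
}

new_waveform <- function(time, value, kind, period) {
  w <- structure(list(time = time, value = value, kind = kind, period = period),
                 class = "waveform")
  validate_waveform(w)
  w
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> kind=%s, T=%.4g s, %d samples, range [%.4g, %.4g]\n",
              x$kind, x$period, length(x$time), min(x$value), max(x$value)))
  invisible(x)
}

validate_waveform <- function(w) {
  stopifnot(inherits(w, "waveform"))
  t <- w$time
  if (any(diff(t) <= 0)) stop_module("boundary_conditions", "waveform times must be strictly increasing")
  if (abs(t[1]) > 1e-12 * w$period) stop_module("boundary_conditions", "waveform must start at t = 0")
  if (abs(t[length(t)] - w$period) > 1e-9 * w$period) {
    stop_module("boundary_conditions", "waveform must end at t = T")
  }
  if (!w$kind %in% c("velocity", "massflow")) stop_module("boundary_conditions", "unknown waveform kind")
  if (w$kind == "velocity" && any(w$value <= 0)) {
    stop_module("boundary_conditions", "velocity waveform values must be > 0")
  }
  vr <- max(abs(w$value))
  if (abs(w$value[1] - w$value[length(w$value)]) > 1e-9 * max(vr, 1e-300)) {
    stop_module("boundary_conditions", "waveform must be periodic: value(0) = value(T)")
  }
  invisible(w)
}

#' Pulsatile velocity waveform from PSV/EDV landmarks
#'
#' The shape between the two printed landmarks is a half-sine systolic pulse of
#' duration `systolic_fraction * T` riding on a constant end-diastolic
#' baseline: the simplest continuous periodic waveform whose minimum is EDV and
#' whose maximum is PSV. The cycle starts at end-diastole, so `value(0) = edv`.
#'
#' @param psv peak systolic velocity (m/s).
#' @param edv end diastolic velocity (m/s), `0 < edv < psv`.
#' @param period cardiac cycle duration T (s).
#' @param systolic_fraction fraction of the cycle occupied by the systolic
#'   pulse, in (0, 1). Default 0.3.
#' @param n_samples number of uniform time samples over the cycle (the exact
#'   peak time is inserted so the sampled maximum equals `psv`).
#' @return a `waveform` of kind `"velocity"`.
#' @export
velocity_waveform <- function(psv, edv, period, systolic_fraction = 0.3, n_samples = 101) {
  if (!is.numeric(psv) || !is.numeric(edv) || edv <= 0 || edv >= psv) {
    stop_module("boundary_conditions", "require 0 < edv < psv")
  }
  if (systolic_fraction <= 0 || systolic_fraction >= 1) {
    stop_module("boundary_conditions", "systolic_fraction must lie in (0, 1)")
  }
  if (period <= 0) stop_module("boundary_conditions", "period must be positive")
  ts <- systolic_fraction * period
  t <- sort(c(seq(0, period, length.out = n_samples), ts / 2, ts))
  t <- t[c(TRUE, diff(t) > 1e-9 * period)]  # drop near-duplicate inserted samples
  v <- ifelse(t <= ts, edv + (psv - edv) * sin(pi * t / ts), edv)
  new_waveform(t, v, "velocity", period)
}

#' Convert a velocity waveform to a mass-flow waveform
#'
#' Pointwise conversion `mdot(t) = rho * V(t) * A` with the cross-sectional
#' area at the measurement site. In the planar model the flow rate is per unit
#' out-of-plane depth, so the site area maps to an equivalent channel width
#' times unit depth.
#'
#' @param w a velocity `waveform`.
#' @param area cross-sectional area at the measurement site (m^2).
#' @param props `fluid_props`.
#' @return a `waveform` of kind `"massflow"` (kg/s).
#' @export
mass_flow_waveform <- function(w, area, props = fluid_props()) {
  validate_waveform(w)
  if (w$kind != "velocity") stop_module("boundary_conditions", "input waveform must be of velocity kind")
  if (!is.numeric(area) || area <= 0) stop_module("boundary_conditions", "area must be > 0")
  structure(list(time = w$time, value = props$density * w$value * area,
                 kind = "massflow", period = w$period), class = "waveform")
}

#' Linearly resample a waveform onto new sample times
#'
#' @param w a `waveform`.
#' @param times new sample times (first 0, last T, strictly increasing).
#' @return a `waveform` of the same kind.
#' @export
resample_waveform <- function(w, times) {
  validate_waveform(w)
  v <- stats::approx(w$time, w$value, xout = times, rule = 2)$y
  new_waveform(times, v, w$kind, w$period)
}

#' Parabolic inflow velocity profile for a target mass flow
#'
#' Poiseuille-type profile across a straight boundary segment of width `w`,
#' scaled so its integrated per-unit-depth mass flux equals the target:
#' `v(s) = 1.5 * U * (1 - (2 s / w)^2)` with mean velocity
#' `U = mdot / (rho * w)` and `s` the signed distance from the segment centre.
#'
#' @param target_massflow target mass flow per unit depth (kg/s).
#' @param boundary_width width of the boundary segment (m).
#' @param props `fluid_props`.
#' @return an object of class `inflow_profile` with elements `fun(s)`,
#'   `mean_velocity`, `peak_velocity`, `width`, `massflow`.
#' @export
inflow_velocity_profile <- function(target_massflow, boundary_width, props = fluid_props()) {
  if (!is.numeric(boundary_width) || boundary_width <= 0) {
    stop_module("boundary_conditions", "boundary_width must be > 0")
  }
  u_mean <- target_massflow / (props$density * boundary_width)
  w <- boundary_width
  fun <- function(s) 1.5 * u_mean * (1 - (2 * s / w)^2)
  structure(list(fun = fun, mean_velocity = u_mean, peak_velocity = 1.5 * u_mean,
                 width = w, massflow = target_massflow, density = props$density),
            class = "inflow_profile")
}

#' Write / read a waveform as two-column CSV with a JSON sidecar
#'
#' @param w a `waveform`.
#' @param path CSV path; the sidecar is written next to it as `<path>.json`.
#' @return `path`, invisibly (writer); a `waveform` (reader).
#' @export
write_waveform_csv <- function(w, path) {
  validate_waveform(w)
  utils::write.csv(data.frame(t = w$time, value = w$value), path, row.names = FALSE)
  jsonlite::write_json(list(kind = w$kind, period = w$period,
                            units = if (w$kind == "velocity") "m/s" else "kg/s"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @param path CSV path previously written by [write_waveform_csv()].
#' @export
read_waveform_csv <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  new_waveform(d$t, d$value, meta$kind, meta$period)
}
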