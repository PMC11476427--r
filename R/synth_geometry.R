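# Synthetic planar carotid bifurcation geometries.
#
# The domain is a 2D channel network parameterized by vertical cross-sections:
# a straight common carotid (CCA) inlet segment, a smooth flare (carotid bulb)
# up to the flow-divider apex, and two branches (internal and external carotid,
# ICA / ECA) that spread apart at fixed angles. A stenosis is modelled as a
# smooth cosine-bump narrowing of the ICA so the walls stay differentiable and
# wall shear stays free of spurious singularities.

smoothstep01 <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

#' Generate a synthetic planar carotid bifurcation geometry
#'
#' @param reference_diameters named numeric vector with entries `cca`, `ica`,
#'   `eca`: reference lumen widths in meters.
#' @param stenosis_severity stenosis severity `s` of the ICA branch in
#'   `[0, 0.95)`; the minimal ICA lumen width is `(1 - s)` times the ICA
#'   reference width.
#' @param seed integer seed; generation is deterministic per seed.
#' @return an object of class `bifurcation_geometry`.
#' @export
generate_geometry <- function(reference_diameters = c(cca = 6e-3, ica = 4.5e-3, eca = 3.5e-3),
                              stenosis_severity = 0.3, seed = 1) {
  d <- reference_diameters
  if (!all(c("cca", "ica", "eca") %in% names(d)) || any(d <= 0)) {
    stop_module("synth_data", "reference_diameters must be positive and named cca/ica/eca")
  }
  if (stenosis_severity < 0 || stenosis_severity >= 0.95) {
    stop_module("synth_data", "stenosis severity >= 0.95 rejected (mesh degeneracy); need s in [0, 0.95)")
  }
  u <- with_local_seed(seed, stats::runif(6))
  d_cca <- unname(d["cca"]); d_ica <- unname(d["ica"]); d_eca <- unname(d["eca"])
  y_apex <- (d_eca - d_ica) / 2
  pars <- list(
    d_cca = d_cca, d_ica = d_ica, d_eca = d_eca, y_apex = y_apex,
    severity = stenosis_severity,
    alpha_ica = (20 + 4 * u[1]) * pi / 180,
    alpha_eca = (18 + 4 * u[2]) * pi / 180,
    l_straight = (2.2 + 0.5 * u[3]) * d_cca,
    l_flare = (1.0 + 0.2 * u[4]) * d_cca,
    l_spread = d_cca,
    l_branch = (3.5 + 0.5 * u[5]) * d_cca,
    sten_center = (1.6 + 0.4 * u[6]) * d_cca,
    sten_length = 1.5 * d_ica
  )
  pars$x_inlet <- -(pars$l_straight + pars$l_flare)
  geom <- structure(c(pars, list(seed = seed)), class = "bifurcation_geometry")
  geom$blocks <- bifurcation_blocks(geom)
  geom$boundary <- geometry_boundary_polygon(geom)
  validate_geometry(geom)
  geom
}

# ICA width factor: smooth cosine bump dipping to (1 - s) at the stenosis centre
stenosis_factor <- function(x, center, len, s) {
  f <- rep(1, length(x))
  inside <- abs(x - center) <= len / 2
  f[inside] <- 1 - s / 2 * (1 + cos(2 * pi * (x[inside] - center) / len))
  f
}

bifurcation_blocks <- function(g) {
  lo_upper <- function(x) {
    ifelse(x <= 0, g$y_apex, {
      spread <- x * smoothstep01(x / g$l_spread)
      ci <- g$y_apex + g$d_ica / 2 + tan(g$alpha_ica) * spread
      wi <- g$d_ica * stenosis_factor(x, g$sten_center, g$sten_length, g$severity)
      ci - wi / 2
    })
  }
  hi_upper <- function(x) {
    ifelse(x <= 0, {
      b <- smoothstep01((x + g$l_flare) / g$l_flare)
      (1 - b) * g$d_cca / 2 + b * (g$y_apex + g$d_ica)
    }, {
      spread <- x * smoothstep01(x / g$l_spread)
      ci <- g$y_apex + g$d_ica / 2 + tan(g$alpha_ica) * spread
      wi <- g$d_ica * stenosis_factor(x, g$sten_center, g$sten_length, g$severity)
      ci + wi / 2
    })
  }
  lo_lower <- function(x) {
    ifelse(x <= 0, {
      b <- smoothstep01((x + g$l_flare) / g$l_flare)
      (1 - b) * (-g$d_cca / 2) + b * (g$y_apex - g$d_eca)
    }, {
      spread <- x * smoothstep01(x / g$l_spread)
      g$y_apex - g$d_eca - tan(g$alpha_eca) * spread
    })
  }
  hi_lower <- function(x) {
    ifelse(x <= 0, g$y_apex, {
      spread <- x * smoothstep01(x / g$l_spread)
      g$y_apex - tan(g$alpha_eca) * spread
    })
  }
  list(
    upper = list(name = "upper", x_range = c(g$x_inlet, g$l_branch),
                 x_knots = c(g$x_inlet, -g$l_flare, 0, g$l_branch),
                 lo = lo_upper, hi = hi_upper,
                 tag_left = "inlet", tag_right = "outlet_ica",
                 tag_top = function(x) rep("wall", length(x)),
                 tag_bottom = function(x) ifelse(x >= 0, "wall", NA_character_)),
    lower = list(name = "lower", x_range = c(g$x_inlet, g$l_branch),
                 x_knots = c(g$x_inlet, -g$l_flare, 0, g$l_branch),
                 lo = lo_lower, hi = hi_lower,
                 tag_left = "inlet", tag_right = "outlet_eca",
                 tag_top = function(x) ifelse(x >= 0, "wall", NA_character_),
                 tag_bottom = function(x) rep("wall", length(x)))
  )
}

geometry_boundary_polygon <- function(g, n_per_path = 160) {
  bu <- g$blocks$upper; bl <- g$blocks$lower
  xs_full <- seq(g$x_inlet, g$l_branch, length.out = 2 * n_per_path)
  xs_pos <- seq(0, g$l_branch, length.out = n_per_path)
  xe <- g$l_branch
  poly <- rbind(
    cbind(xs_full, bl$lo(xs_full)),                       # bottom outer wall ->
    c(xe, bl$hi(xe)),                                     # ECA outlet
    cbind(rev(xs_pos), bl$hi(rev(xs_pos))),               # divider lower side <- to apex
    cbind(xs_pos, bu$lo(xs_pos)),                         # divider upper side -> to ICA outlet
    c(xe, bu$hi(xe)),                                     # ICA outlet
    cbind(rev(xs_full), bu$hi(rev(xs_full)))              # top outer wall <- back to inlet
  )
  # drop consecutive duplicates (apex appears twice)
  keep <- c(TRUE, rowSums(abs(diff(poly))) > 1e-15)
  unname(poly[keep, , drop = FALSE])
}

validate_geometry <- function(g) {
  stopifnot(inherits(g, "bifurcation_geometry"))
  xs <- seq(1e-9, g$l_branch, length.out = 400)
  bu <- g$blocks$upper; bl <- g$blocks$lower
  gap <- bu$lo(xs) - bl$hi(xs)
  if (any(gap < -1e-12)) stop_module("synth_data", "flow-divider walls intersect")
  wu <- bu$hi(xs) - bu$lo(xs); wl <- bl$hi(xs) - bl$lo(xs)
  if (any(wu <= 0) || any(wl <= 0)) stop_module("synth_data", "branch width must stay positive")
  wmin <- min(wu)
  target <- (1 - g$severity) * g$d_ica
  if (abs(wmin - target) > 0.01 * target) {
    stop_module("synth_data", "minimal ICA width %.3g deviates >1%% from (1-s)*reference %.3g",
                wmin, target)
  }
  if (abs(polygon_area(g$boundary)) <= 0) stop_module("synth_data", "degenerate boundary polygon")
  invisible(g)
}

#' @export
print.bifurcation_geometry <- function(x, ...) {
  cat(sprintf("<bifurcation_geometry> CCA %.2f mm / ICA %.2f mm / ECA %.2f mm, stenosis %.0f%%\n",
              1e3 * x$d_cca, 1e3 * x$d_ica, 1e3 * x$d_eca, 100 * x$severity))
  cat(sprintf("  domain x in [%.1f, %.1f] mm, seed %d\n",
              1e3 * x$x_inlet, 1e3 * x$l_branch, x$seed))
  invisible(x)
}

#' Straight 2D channel geometry for solver benchmarks
#'
#' @param length channel length (m).
#' @param width channel width (m).
#' @return a `channel_geometry` usable with [mesh_domain()]; the single outlet
#'   carries the `outlet_ica` tag (traction-free, zero-pressure outlet).
#' @export
straight_channel_geometry <- function(length, width) {
  stopifnot(length > 0, width > 0)
  blk <- list(name = "channel", x_range = c(0, length), x_knots = c(0, length),
              lo = function(x) rep(-width / 2, base::length(x)),
              hi = function(x) rep(width / 2, base::length(x)),
              tag_left = "inlet", tag_right = "outlet_ica",
              tag_top = function(x) rep("wall", base::length(x)),
              tag_bottom = function(x) rep("wall", base::length(x)))
  structure(list(length = length, width = width, blocks = list(channel = blk)),
            class = "channel_geometry")
}

#' Write geometry boundary polygon as CSV with JSON metadata
#' @param geom a `bifurcation_geometry`.
#' @param path CSV path (x, y in meters); metadata goes to `<path>.json`.
#' @export
write_geometry_csv <- function(geom, path) {
  stopifnot(inherits(geom, "bifurcation_geometry"))
  utils::write.csv(data.frame(x = geom$boundary[, 1], y = geom$boundary[, 2]),
                   path, row.names = FALSE)
  meta <- list(d_cca = geom$d_cca, d_ica = geom$d_ica, d_eca = geom$d_eca,
               severity = geom$severity, seed = geom$seed,
               stenosis_center = geom$sten_center, stenosis_length = geom$sten_length)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
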