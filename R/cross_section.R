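# Plaque-bearing arterial cross-sections at the site of maximum plaque burden,
# and their region-tagged structural meshes.
#
# The cross-section is an annular wall ring (lumen radius to outer radius)
# containing a fibrous plaque shaped as an annular sector, separated from the
# lumen by a fibrous cap of wall tissue. Since the printed plaque burden has no
# quantitative definition, the generator exposes the plaque area fraction as
# its stand-in.

#' Construct a cross-section geometry
#'
#' @param r_lumen lumen radius (m).
#' @param wall_thickness thickness of the wall ring (m).
#' @param plaque `NULL` for a homogeneous ring, or a list with `theta0`
#'   (start angle, rad), `arc` (angular extent, rad), `cap` (cap thickness, m)
#'   and `thickness` (radial plaque thickness, m).
#' @return an object of class `cross_section_geometry`.
#' @export
cross_section_geometry <- function(r_lumen, wall_thickness, plaque = NULL) {
  if (r_lumen <= 0 || wall_thickness <= 0) {
    stop_module("synth_data", "lumen radius and wall thickness must be positive")
  }
  r_outer <- r_lumen + wall_thickness
  if (!is.null(plaque)) {
    if (plaque$cap <= 0) stop_module("synth_data", "cap thickness must be > 0")
    if (plaque$arc <= 0) stop_module("synth_data", "plaque must be non-degenerate: arc extent > 0 required")
    if (plaque$arc > 330 * pi / 180) stop_module("synth_data", "plaque arc extent must be <= 330 degrees")
    if (plaque$thickness <= 0) stop_module("synth_data", "plaque thickness must be > 0")
    if (plaque$cap + plaque$thickness >= 0.95 * wall_thickness) {
      stop_module("synth_data",
                  "invariant violated: plaque contour not strictly inside the wall ring (cap + thickness too large)")
    }
    plaque$r_inner <- r_lumen + plaque$cap
    plaque$r_outer <- plaque$r_inner + plaque$thickness
  }
  g <- structure(list(r_lumen = r_lumen, r_outer = r_outer,
                      wall_thickness = wall_thickness, plaque = plaque),
                 class = "cross_section_geometry")
  g$contours <- cross_section_contours(g)
  g
}

circle_polygon <- function(r, n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(r * cos(th), r * sin(th))
}

cross_section_contours <- function(g) {
  out <- list(lumen = circle_polygon(g$r_lumen), outer_wall = circle_polygon(g$r_outer),
              plaques = list())
  if (!is.null(g$plaque)) {
    p <- g$plaque
    n <- max(48, ceiling(p$arc / (pi / 180)))
    th <- seq(p$theta0, p$theta0 + p$arc, length.out = n)
    poly <- rbind(cbind(p$r_inner * cos(th), p$r_inner * sin(th)),
                  cbind(p$r_outer * cos(rev(th)), p$r_outer * sin(rev(th))))
    out$plaques <- list(poly)
  }
  out
}

#' Generate a random plaque-bearing cross-section
#'
#' @param wall_thickness wall ring thickness (m).
#' @param plaque_arc_extent plaque angular extent in degrees, in (0, 330].
#' @param cap_thickness fibrous cap thickness (m), > 0.
#' @param seed integer seed; generation is deterministic per seed.
#' @return a `cross_section_geometry` with one plaque.
#' @export
generate_cross_section <- function(wall_thickness = 1.5e-3, plaque_arc_extent = 120,
                                   cap_thickness = 2.5e-4, seed = 1) {
  if (plaque_arc_extent <= 0) {
    stop_module("synth_data", "plaque must be non-degenerate: arc extent > 0 required")
  }
  if (plaque_arc_extent > 330) stop_module("synth_data", "plaque arc extent must be <= 330 degrees")
  u <- with_local_seed(seed, stats::runif(3))
  r_lumen <- 2e-3 * (0.9 + 0.2 * u[1])
  thickness <- (0.50 + 0.15 * u[2]) * (wall_thickness - cap_thickness)
  cross_section_geometry(r_lumen, wall_thickness,
                         plaque = list(theta0 = 2 * pi * u[3],
                                       arc = plaque_arc_extent * pi / 180,
                                       cap = cap_thickness, thickness = thickness))
}

#' Plaque area fraction (stand-in for plaque burden)
#' @param geom a `cross_section_geometry`.
#' @return plaque area divided by wall-ring area.
#' @export
plaque_area_fraction <- function(geom) {
  stopifnot(inherits(geom, "cross_section_geometry"))
  if (is.null(geom$plaque)) return(0)
  p <- geom$plaque
  a_plq <- p$arc / 2 * (p$r_outer^2 - p$r_inner^2)
  a_ring <- pi * (geom$r_outer^2 - geom$r_lumen^2)
  a_plq / a_ring
}

#' @export
print.cross_section_geometry <- function(x, ...) {
  cat(sprintf("<cross_section_geometry> lumen r %.2f mm, wall %.2f mm",
              1e3 * x$r_lumen, 1e3 * x$wall_thickness))
  if (!is.null(x$plaque)) {
    cat(sprintf(", plaque arc %.0f deg / cap %.2f mm",
                x$plaque$arc * 180 / pi, 1e3 * x$plaque$cap))
  }
  cat("\n")
  invisible(x)
}

#' Write cross-section contours as a multi-contour CSV with region labels
#' @param geom a `cross_section_geometry`.
#' @param path CSV path with columns `region`, `contour`, `x`, `y`.
#' @export
write_cross_section_csv <- function(geom, path) {
  ct <- geom$contours
  rows <- list(data.frame(region = "lumen", contour = 1L, x = ct$lumen[, 1], y = ct$lumen[, 2]),
               data.frame(region = "wall", contour = 1L, x = ct$outer_wall[, 1], y = ct$outer_wall[, 2]))
  for (k in seq_along(ct$plaques)) {
    rows[[length(rows) + 1L]] <- data.frame(region = "plaque", contour = k,
                                            x = ct$plaques[[k]][, 1], y = ct$plaques[[k]][, 2])
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

# --- structural mesh ---------------------------------------------------------

# radial breakpoints within [a, b] at target size h, with half-size layers at
# both ends (graded refinement standing in for boundary-layer inflation)
graded_breaks <- function(a, b, h) {
  n <- max(3, ceiling((b - a) / h))
  u <- c(0, 0.5, seq(1.5, n - 1.5, by = 1), n - 0.5, n) / n
  u <- sort(unique(pmin(pmax(u, 0), 1)))
  a + (b - a) * u
}

#' Mesh a cross-section into region-tagged quadratic triangles
#'
#' Polar structured mesh: angular columns and radial layers, with radial
#' breakpoints aligned to the lumen, cap, plaque and outer interfaces so that
#' plaque and wall elements share interface nodes (bonded contact by
#' construction). Layers adjacent to the lumen and plaque interfaces are
#' halved in thickness (graded refinement standing in for inflation layers).
#'
#' @param geom a `cross_section_geometry`.
#' @param face_size maximum element face size (m). Default 0.05 mm.
#' @return an object of class `structural_mesh` with fields `nodes`, `tris`,
#'   `region` (per-element, `wall` or `plaque`), `cap_band` (per-element flag
#'   for wall elements between lumen and plaque), `boundary` (tagged edges
#'   `lumen` / `outer`).
#' @export
mesh_cross_section <- function(geom, face_size = 5e-5) {
  stopifnot(inherits(geom, "cross_section_geometry"))
  if (face_size <= 0) stop_module("plaque_stress", "face_size must be > 0")
  h <- face_size / sqrt(2) / 1.15
  ntheta <- max(12, ceiling(2 * pi * geom$r_outer / h))
  th <- seq(0, 2 * pi, length.out = ntheta + 1)[-(ntheta + 1)]
  p <- geom$plaque
  if (!is.null(p)) {
    th0 <- p$theta0 %% (2 * pi); th1 <- (p$theta0 + p$arc) %% (2 * pi)
    th <- sort(unique(c(th, th0, th1)))
    th <- th[c(TRUE, diff(th) > 1e-9)]
    if ((2 * pi - th[length(th)]) + th[1] < 1e-9) th <- th[-length(th)]
    ntheta <- length(th)
    rbreaks <- c(graded_breaks(geom$r_lumen, p$r_inner, h),
                 graded_breaks(p$r_inner, p$r_outer, h)[-1],
                 graded_breaks(p$r_outer, geom$r_outer, h)[-1])
  } else {
    rbreaks <- graded_breaks(geom$r_lumen, geom$r_outer, h)
  }
  nr <- length(rbreaks)
  nodes <- cbind(rep(rbreaks, each = ntheta) * rep(cos(th), nr),
                 rep(rbreaks, each = ntheta) * rep(sin(th), nr))
  nid <- function(i, j) (j - 1L) * ntheta + ((i - 1L) %% ntheta) + 1L
  tris <- matrix(0L, nrow = 2 * ntheta * (nr - 1), ncol = 3)
  k <- 0L
  for (j in seq_len(nr - 1)) {
    i <- seq_len(ntheta)
    a <- nid(i, j); b <- nid(i + 1L, j); c2 <- nid(i + 1L, j + 1L); d2 <- nid(i, j + 1L)
    # consistent chirality preserves rotational symmetry of the mesh
    tris[k + seq_len(ntheta), ] <- cbind(a, b, c2)
    tris[k + ntheta + seq_len(ntheta), ] <- cbind(a, c2, d2)
    k <- k + 2L * ntheta
  }
  # region by element centroid
  cx <- (nodes[tris[, 1], 1] + nodes[tris[, 2], 1] + nodes[tris[, 3], 1]) / 3
  cy <- (nodes[tris[, 1], 2] + nodes[tris[, 2], 2] + nodes[tris[, 3], 2]) / 3
  rc <- sqrt(cx^2 + cy^2); ac <- atan2(cy, cx) %% (2 * pi)
  region <- rep("wall", nrow(tris))
  cap_band <- rep(FALSE, nrow(tris))
  if (!is.null(p)) {
    in_arc <- angle_in_arc(ac, p$theta0, p$arc)
    region[in_arc & rc >= p$r_inner & rc <= p$r_outer] <- "plaque"
    cap_band[in_arc & rc < p$r_inner] <- TRUE
  }
  i <- seq_len(ntheta)
  boundary <- rbind(
    data.frame(n1 = nid(i, 1L), n2 = nid(i + 1L, 1L), tag = "lumen"),
    data.frame(n1 = nid(i, nr), n2 = nid(i + 1L, nr), tag = "outer")
  )
  m <- structure(list(nodes = nodes, tris = tris, region = region, cap_band = cap_band,
                      boundary = boundary, face_size = face_size, ntheta = ntheta,
                      geom = geom),
                 class = c("structural_mesh", "fem_mesh"))
  orient_and_validate_mesh(m, h_max = NULL)
}

angle_in_arc <- function(theta, theta0, arc) {
  rel <- (theta - theta0) %% (2 * pi)
  rel <= arc + 1e-12
}
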