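# Plane-strain hyperelastic finite-element analysis of the plaque-bearing
# cross-section: total-Lagrangian formulation, quadratic triangles, Newton
# iteration with incremental loading, follower pressure on the lumen boundary,
# frictionless (zero normal displacement) support on the outer perimeter.

edge_gauss3 <- function() {
  # 3-point Gauss on [0,1]
  x <- c(0.5 - sqrt(3 / 5) / 2, 0.5, 0.5 + sqrt(3 / 5) / 2)
  w <- c(5, 8, 5) / 18
  list(x = x, w = w)
}

# quadratic edge shape functions at parameter xi in [0,1]; node order (end1,
# end2, midpoint) matching boundary rows (n1, n2, mid)
edge_shapes <- function(xi) {
  N <- cbind((1 - xi) * (1 - 2 * xi), xi * (2 * xi - 1), 4 * xi * (1 - xi))
  dN <- cbind(4 * xi - 3, 4 * xi - 1, 4 - 8 * xi)
  list(N = N, dN = dN)
}

# internal force vector per element (m x 12 matrix, dofs [ux1..ux6, uy1..uy6])
structural_internal_force <- function(st, ue) {
  pre <- st$pre
  m <- nrow(st$t2)
  f <- matrix(0, m, 12)
  uex <- ue[, 1:6]; uey <- ue[, 7:12]
  for (q in seq_len(pre$nq)) {
    gx <- pre$gx[[q]]; gy <- pre$gy[[q]]
    F11 <- 1 + rowSums(uex * gx); F12 <- rowSums(uex * gy)
    F21 <- rowSums(uey * gx);     F22 <- 1 + rowSums(uey * gy)
    detF <- F11 * F22 - F12 * F21
    if (any(detF <= 0)) return(NULL)   # signals element inversion
    C11 <- F11^2 + F21^2
    C12 <- F11 * F12 + F21 * F22
    C22 <- F12^2 + F22^2
    S11 <- S12 <- S22 <- numeric(m)
    for (rg in names(st$mat_idx)) {
      idx <- st$mat_idx[[rg]]
      S <- mr_stress_ps(st$materials[[rg]], C11[idx], C12[idx], C22[idx])
      S11[idx] <- S$S11; S12[idx] <- S$S12; S22[idx] <- S$S22
    }
    P11 <- F11 * S11 + F12 * S12; P12 <- F11 * S12 + F12 * S22
    P21 <- F21 * S11 + F22 * S12; P22 <- F21 * S12 + F22 * S22
    wdet <- pre$w[q] * pre$detJ
    f[, 1:6] <- f[, 1:6] + (P11 * wdet) * gx + (P12 * wdet) * gy
    f[, 7:12] <- f[, 7:12] + (P21 * wdet) * gx + (P22 * wdet) * gy
  }
  f
}

# follower pressure load on the lumen boundary: consistent nodal forces on the
# deformed edge; returns (nedge x 6) forces for dofs [x1, x2, xm, y1, y2, ym]
lumen_pressure_force <- function(st, u, pressure) {
  ed <- st$lumen_edges
  if (!nrow(ed$ids)) return(NULL)
  g3 <- edge_gauss3()
  sh <- edge_shapes(g3$x)
  n2 <- st$n_p2
  xs <- matrix(st$coords[ed$ids, 1] + u[ed$ids], ncol = 3)         # deformed x of (n1, n2, mid)
  ys <- matrix(st$coords[ed$ids, 2] + u[ed$ids + n2], ncol = 3)
  f <- matrix(0, nrow(xs), 6)
  for (q in 1:3) {
    dxd <- xs %*% sh$dN[q, ]; dyd <- ys %*% sh$dN[q, ]
    # normal-times-jacobian along the edge; ed$sgn fixes the outward direction
    nx <- dyd * ed$sgn; ny <- -dxd * ed$sgn
    for (a in 1:3) {
      f[, a] <- f[, a] + g3$w[q] * pressure * sh$N[q, a] * nx
      f[, a + 3] <- f[, a + 3] + g3$w[q] * pressure * sh$N[q, a] * ny
    }
  }
  f
}

# scatter-add element force matrix into a global residual vector
scatter_forces <- function(vec, rows, f) {
  for (k in seq_len(ncol(rows))) {
    vec <- vec + unname(tapply(f[, k], rows[, k], sum)[as.character(seq_along(vec))])
  }
  vec
}

accumulate_global <- function(ndof, rows, f) {
  out <- numeric(ndof)
  idx <- as.vector(rows)
  vals <- as.vector(f)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Solve the plane-strain hyperelastic cross-section problem
#'
#' Newton iteration on the total-Lagrangian weak form with a
#' pressure-follower load on the lumen boundary, zero normal displacement and
#' free tangential slip (frictionless support) on the outer boundary, and
#' materials assigned per region (plaque bonded to the wall through shared
#' interface nodes). The load is applied in increments with automatic halving
#' on divergence.
#'
#' @param mesh a `structural_mesh` from [mesh_cross_section()].
#' @param materials named list of `material_mr`, one per region present
#'   (`wall`, `plaque`).
#' @param luminal_pressure absolute pressure applied on the lumen (Pa), >= 0.
#' @param n_increments initial number of load increments.
#' @param newton_tol relative residual convergence criterion.
#' @param max_newton Newton iterations per increment.
#' @return an object of class `structural_solution`.
#' @export
solve_structural <- function(mesh, materials, luminal_pressure,
                             n_increments = 5, newton_tol = 1e-6, max_newton = 30) {
  stopifnot(inherits(mesh, "structural_mesh"))
  if (luminal_pressure < 0) stop_module("plaque_stress", "pressure must be >= 0")
  regions <- unique(mesh$region)
  miss <- setdiff(regions, names(materials))
  if (length(miss)) stop_module("plaque_stress", "no material for region(s): %s", paste(miss, collapse = ", "))

  p2m <- p2_mesh(mesh)
  pre <- precompute_p2(p2m, tri_quad_rule(4))
  n2 <- p2m$n_p2
  ndof <- 2L * n2
  lum <- p2m$boundary[p2m$boundary$tag == "lumen", , drop = FALSE]
  # fixed outward sign per lumen edge, from the reference configuration
  g3 <- edge_gauss3(); shm <- edge_shapes(0.5)
  dx0 <- cbind(p2m$coords[lum$n1, 1], p2m$coords[lum$n2, 1], p2m$coords[lum$mid, 1]) %*% shm$dN[1, ]
  dy0 <- cbind(p2m$coords[lum$n1, 2], p2m$coords[lum$n2, 2], p2m$coords[lum$mid, 2]) %*% shm$dN[1, ]
  midx <- p2m$coords[lum$mid, 1]; midy <- p2m$coords[lum$mid, 2]
  sgn <- ifelse(dy0 * midx - dx0 * midy > 0, 1, -1)  # push away from the lumen centre

  st <- list(
    t2 = p2m$t2, coords = p2m$coords, n_p2 = n2, pre = pre,
    materials = materials,
    mat_idx = split(seq_len(nrow(p2m$t2)), mesh$region),
    lumen_edges = list(ids = cbind(lum$n1, lum$n2, lum$mid), sgn = sgn)
  )
  rows_el <- cbind(st$t2, st$t2 + n2)                     # m x 12 global dofs
  rows_lum <- cbind(lum$n1, lum$n2, lum$mid, lum$n1 + n2, lum$n2 + n2, lum$mid + n2)

  # frictionless outer support as an exact constraint: rotate the dofs of
  # outer-boundary nodes into (tangent, normal) components and fix the normal
  # one; one tangential dof is pinned to remove the free rigid rotation
  outer <- p2m$boundary[p2m$boundary$tag == "outer", , drop = FALSE]
  onode <- unique(c(outer$n1, outer$n2, outer$mid))
  onrm <- p2m$coords[onode, , drop = FALSE]
  onrm <- onrm / sqrt(rowSums(onrm^2))          # outward radial normal
  # u = Tmat %*% y: at outer nodes y[i] = tangential, y[i + n2] = normal
  tang <- cbind(-onrm[, 2], onrm[, 1])
  Tmat <- Matrix::sparseMatrix(
    i = c(setdiff(seq_len(ndof), c(onode, onode + n2)),
          onode, onode + n2,           # column y_t
          onode, onode + n2),          # column y_n
    j = c(setdiff(seq_len(ndof), c(onode, onode + n2)),
          onode, onode,
          onode + n2, onode + n2),
    x = c(rep(1, ndof - 2 * length(onode)),
          tang[, 1], tang[, 2],
          onrm[, 1], onrm[, 2]),
    dims = c(ndof, ndof))
  fixed_dofs <- c(onode + n2, onode[1])   # all normal components + one tangential

  gather_ue <- function(u) matrix(u[rows_el], nrow(rows_el), 12)
  residual <- function(u, p_now) {
    fint <- structural_internal_force(st, gather_ue(u))
    if (is.null(fint)) return(NULL)
    R <- accumulate_global(ndof, rows_el, fint)
    if (p_now > 0) {
      fl <- lumen_pressure_force(st, u, p_now)
      R <- R - accumulate_global(ndof, rows_lum, fl)
    }
    R
  }
  ij_el <- block_indices(rows_el, rows = rows_el, cols = rows_el)
  ij_lum <- if (nrow(lum)) block_indices(rows_lum, rows = rows_lum, cols = rows_lum) else NULL
  hchar <- sqrt(mean(pre$detJ) / 2)
  eps_fd <- 1e-6 * hchar   # perturbation strain ~1e-6: central differences

  tangent <- function(u, p_now) {
    ue <- gather_ue(u)
    f0 <- structural_internal_force(st, ue)
    m <- nrow(ue)
    Kel <- matrix(0, m, 144)
    for (k in 1:12) {
      up <- ue; up[, k] <- up[, k] + eps_fd
      um <- ue; um[, k] <- um[, k] - eps_fd
      fp <- structural_internal_force(st, up)
      fm <- structural_internal_force(st, um)
      Kel[, ((k - 1) * 12 + 1):(k * 12)] <-
        if (is.null(fp) && is.null(fm)) 0 else
        if (is.null(fp)) (f0 - fm) / eps_fd else
        if (is.null(fm)) (fp - f0) / eps_fd else (fp - fm) / (2 * eps_fd)
    }
    xs <- as.vector(Kel); is <- ij_el$i; js <- ij_el$j
    if (p_now > 0 && !is.null(ij_lum)) {
      fl0 <- lumen_pressure_force(st, u, p_now)
      Klm <- matrix(0, nrow(fl0), 36)
      dofs_l <- cbind(st$lumen_edges$ids, st$lumen_edges$ids + n2)
      for (k in 1:6) {
        upv <- u; umv <- u
        upv[dofs_l[, k]] <- upv[dofs_l[, k]] + eps_fd
        umv[dofs_l[, k]] <- umv[dofs_l[, k]] - eps_fd
        flp <- lumen_pressure_force(st, upv, p_now)
        flm <- lumen_pressure_force(st, umv, p_now)
        Klm[, ((k - 1) * 6 + 1):(k * 6)] <- -(flp - flm) / (2 * eps_fd)
      }
      xs <- c(xs, as.vector(Klm)); is <- c(is, ij_lum$i); js <- c(js, ij_lum$j)
    }
    Matrix::sparseMatrix(i = is, j = js, x = xs, dims = c(ndof, ndof))
  }

  u <- numeric(ndof)
  p_applied <- 0
  dP <- luminal_pressure / n_increments
  halvings <- 0L
  increments_done <- 0L
  last_res <- NA_real_
  while (p_applied < luminal_pressure - 1e-12 * max(luminal_pressure, 1)) {
    p_target <- min(luminal_pressure, p_applied + dP)
    u_try <- u
    ok <- FALSE
    ref_scale <- max(abs(p_target) * sum(abs(st$lumen_edges$sgn)) * hchar, 1e-12)
    res_norm <- function(u_) {
      R <- residual(u_, p_target)
      if (is.null(R)) return(list(res = Inf, R = NULL))
      # reactions at constrained dofs are excluded from the convergence norm
      Ry <- as.numeric(Matrix::t(Tmat) %*% R)
      Ry[fixed_dofs] <- 0
      fl <- lumen_pressure_force(st, u_, p_target)
      fext_norm <- if (is.null(fl)) 0 else sqrt(sum(fl^2))
      list(res = sqrt(sum(Ry^2)) / max(fext_norm, 1e-300), R = R)
    }
    cur <- res_norm(u_try)
    for (it in seq_len(max_newton)) {
      if (is.null(cur$R)) break
      last_res <- cur$res
      if (cur$res < newton_tol) { ok <- TRUE; break }
      K <- tangent(u_try, p_target)
      # solve in rotated coordinates with the normal components constrained
      Ky <- Matrix::t(Tmat) %*% K %*% Tmat
      Ry <- as.numeric(Matrix::t(Tmat) %*% cur$R)
      free <- setdiff(seq_len(ndof), fixed_dofs)
      dy <- numeric(ndof)
      dy[free] <- tryCatch(as.numeric(Matrix::solve(Ky[free, free], -Ry[free])),
                           error = function(e) rep(NA_real_, length(free)))
      if (!all(is.finite(dy))) break
      du <- as.numeric(Tmat %*% dy)
      # backtracking line search on the residual norm
      accepted <- FALSE
      for (alpha in c(1, 0.5, 0.25, 0.125, 0.0625)) {
        trial <- res_norm(u_try + alpha * du)
        if (is.finite(trial$res) && (trial$res < cur$res || alpha == 0.0625)) {
          u_try <- u_try + alpha * du
          cur <- trial
          accepted <- is.finite(trial$res)
          break
        }
      }
      if (!accepted) break
    }
    if (ok) {
      u <- u_try
      p_applied <- p_target
      increments_done <- increments_done + 1L
    } else {
      halvings <- halvings + 1L
      dP <- dP / 2
      if (halvings > 6) {
        stop_module("plaque_stress",
                    "Newton failed to converge after %d increment halvings (last residual %.2e)",
                    halvings, last_res)
      }
    }
  }
  if (luminal_pressure == 0) {
    increments_done <- 1L
    last_res <- 0
  }

  sol <- structural_postprocess(st, p2m, mesh, u, luminal_pressure)
  sol$increments <- increments_done
  sol$residual <- last_res
  sol$outer_normal_disp <- max(abs(u[onode] * onrm[, 1] + u[onode + n2] * onrm[, 2]))
  sol
}

# per-element Cauchy stress summaries and nodal displacement magnitudes
structural_postprocess <- function(st, p2m, mesh, u, pressure) {
  pre <- st$pre
  m <- nrow(st$t2)
  ue <- matrix(u[cbind(st$t2, st$t2 + st$n_p2)], m, 12)
  uex <- ue[, 1:6]; uey <- ue[, 7:12]
  smax <- rep(-Inf, m); vmmax <- rep(0, m)
  comp <- matrix(0, m, 4)  # quadrature-averaged (s11, s12, s22, s33)
  for (q in seq_len(pre$nq)) {
    gx <- pre$gx[[q]]; gy <- pre$gy[[q]]
    F11 <- 1 + rowSums(uex * gx); F12 <- rowSums(uex * gy)
    F21 <- rowSums(uey * gx);     F22 <- 1 + rowSums(uey * gy)
    C11 <- F11^2 + F21^2; C12 <- F11 * F12 + F21 * F22; C22 <- F12^2 + F22^2
    S11 <- S12 <- S22 <- S33 <- J <- numeric(m)
    for (rg in names(st$mat_idx)) {
      idx <- st$mat_idx[[rg]]
      S <- mr_stress_ps(st$materials[[rg]], C11[idx], C12[idx], C22[idx])
      S11[idx] <- S$S11; S12[idx] <- S$S12; S22[idx] <- S$S22; S33[idx] <- S$S33
      J[idx] <- S$J
    }
    s11 <- (F11 * (F11 * S11 + F12 * S12) + F12 * (F11 * S12 + F12 * S22)) / J
    s12 <- (F21 * (F11 * S11 + F12 * S12) + F22 * (F11 * S12 + F12 * S22)) / J
    s22 <- (F21 * (F21 * S11 + F22 * S12) + F22 * (F21 * S12 + F22 * S22)) / J
    s33 <- S33 / J
    cen <- sqrt(((s11 - s22) / 2)^2 + s12^2)
    p1 <- (s11 + s22) / 2 + cen
    p2 <- (s11 + s22) / 2 - cen
    smax <- pmax(smax, pmax(p1, s33))
    vmmax <- pmax(vmmax, sqrt(0.5 * ((p1 - p2)^2 + (p2 - s33)^2 + (s33 - p1)^2)))
    comp <- comp + cbind(s11, s12, s22, s33) / pre$nq
  }
  umag <- sqrt(u[seq_len(st$n_p2)]^2 + u[st$n_p2 + seq_len(st$n_p2)]^2)
  cx <- (mesh$nodes[mesh$tris[, 1], 1] + mesh$nodes[mesh$tris[, 2], 1] + mesh$nodes[mesh$tris[, 3], 1]) / 3
  cy <- (mesh$nodes[mesh$tris[, 1], 2] + mesh$nodes[mesh$tris[, 2], 2] + mesh$nodes[mesh$tris[, 3], 2]) / 3
  structure(list(
    mesh = mesh, p2 = p2m, u = u, displacement_magnitude = umag,
    principal_max = smax, von_mises_max = vmmax, stress_components = comp,
    element_centroid = cbind(cx, cy), region = mesh$region, cap_band = mesh$cap_band,
    pressure = pressure
  ), class = "structural_solution")
}

#' @export
print.structural_solution <- function(x, ...) {
  cat(sprintf("<structural_solution> p = %.3g Pa, max |u| = %.3g m, max principal stress = %.3g Pa\n",
              x$pressure, max(x$displacement_magnitude), max(x$principal_max)))
  invisible(x)
}

#' Plaque structural stress and maximum deformation
#'
#' PSS is the maximum first principal Cauchy stress over plaque elements and
#' the fibrous-cap band (wall elements between lumen and plaque); maximum von
#' Mises stress is reported alongside as a sensitivity companion.
#'
#' @param sol a converged `structural_solution`.
#' @return list with `pss` (Pa), `location` (region tag and coordinates),
#'   `max_deformation` (m) and `max_von_mises` (Pa).
#' @export
plaque_structural_stress <- function(sol) {
  stopifnot(inherits(sol, "structural_solution"))
  sel <- sol$region == "plaque" | sol$cap_band
  if (!any(sel)) sel <- rep(TRUE, length(sol$region))   # homogeneous ring
  smax <- sol$principal_max
  smax[!sel] <- -Inf
  k <- which.max(smax)
  list(pss = max(sol$principal_max[sel], 0),
       location = list(region = if (sol$cap_band[k]) "cap" else sol$region[k],
                       x = sol$element_centroid[k, 1], y = sol$element_centroid[k, 2]),
       max_deformation = max(sol$displacement_magnitude),
       max_von_mises = max(sol$von_mises_max[sel]))
}
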