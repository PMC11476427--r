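# Transient incompressible Newtonian flow on a meshed planar bifurcation:
# Taylor-Hood P2/P1 mixed elements, implicit Euler time stepping, Picard
# linearization of the convective term. Boundary scheme: prescribed velocity
# profiles at the CCA inlet and the ECA outlet, traction-free (zero-pressure)
# ICA outlet, no-slip walls.

#' Flow boundary condition: target mass flow at a tagged boundary
#'
#' @param massflow either a constant mass flow per unit depth (kg/s) or a
#'   `waveform` of kind `"massflow"`.
#' @param tag tagged boundary the condition applies to.
#' @return an object of class `flow_bc`.
#' @export
flow_bc <- function(massflow, tag = "inlet") {
  if (inherits(massflow, "waveform")) {
    if (massflow$kind != "massflow") stop_module("flow_sim", "flow_bc needs a massflow waveform")
  } else if (!is.numeric(massflow) || length(massflow) != 1L) {
    stop_module("flow_sim", "massflow must be a waveform or a single number")
  }
  structure(list(massflow = massflow, tag = tag), class = "flow_bc")
}

bc_massflow_at <- function(bc, t, period = NULL) {
  if (inherits(bc$massflow, "waveform")) {
    w <- bc$massflow
    tm <- t %% w$period
    stats::approx(w$time, w$value, xout = tm, rule = 2)$y
  } else {
    bc$massflow
  }
}

# geometry of a Dirichlet boundary: width, centre and P2 node ids
dirichlet_boundary_info <- function(p2m, tag) {
  bnd <- p2m$boundary[p2m$boundary$tag == tag, , drop = FALSE]
  if (!nrow(bnd)) stop_module("flow_sim", "no boundary edges tagged '%s'", tag)
  ids <- unique(c(bnd$n1, bnd$n2, bnd$mid))
  y <- p2m$coords[ids, 2]
  list(ids = ids, y = y, width = max(y) - min(y), center = (max(y) + min(y)) / 2)
}

assemble_constant_part <- function(p2m, pre, props, dt = NULL) {
  t2 <- p2m$t2
  n2 <- p2m$n_p2
  m <- nrow(t2)
  mu <- props$viscosity; rho <- props$density
  gx <- pre$gx; gy <- pre$gy
  w <- pre$w; detJ <- pre$detJ

  k11 <- outer_accumulate(w, detJ, gx, gx) * 2 * mu +
    outer_accumulate(w, detJ, gy, gy) * mu
  k22 <- outer_accumulate(w, detJ, gx, gx) * mu +
    outer_accumulate(w, detJ, gy, gy) * 2 * mu
  k12 <- outer_accumulate(w, detJ, gy, gx) * mu      # column u_y in row v_x
  k21 <- outer_accumulate(w, detJ, gx, gy) * mu
  # consistent P2 mass (for the rho/dt term and the RHS)
  Nlist <- lapply(seq_len(pre$nq), function(q) matrix(pre$N[q, ], m, 6, byrow = TRUE))
  mass <- outer_accumulate(w, detJ, Nlist, Nlist)
  if (!is.null(dt)) {
    k11 <- k11 + mass * (rho / dt)
    k22 <- k22 + mass * (rho / dt)
  }
  # pressure blocks: momentum -(p, div v), continuity (q, div u)
  P1list <- lapply(seq_len(pre$nq), function(q) matrix(pre$P1[q, ], m, 3, byrow = TRUE))
  gxp <- outer_accumulate(w, detJ, gx, P1list)   # m x 18, entry (a, k)
  gyp <- outer_accumulate(w, detJ, gy, P1list)

  ij11 <- block_indices(t2)
  ij12 <- block_indices(t2, col_offset = n2)
  ij21 <- block_indices(t2, row_offset = n2)
  ij22 <- block_indices(t2, row_offset = n2, col_offset = n2)
  t1p <- p2m$mesh$tris + 2L * n2
  ijB1 <- block_indices(t2, rows = t2, cols = t1p)                      # (v_x, p)
  ijB2 <- block_indices(t2, rows = t2, cols = t1p); ijB2$i <- ijB2$i + n2
  ijD1 <- list(i = ijB1$j, j = ijB1$i)                                  # (q, u_x)
  ijD2 <- list(i = ijB2$j, j = ijB2$i)

  list(
    i = c(ij11$i, ij12$i, ij21$i, ij22$i, ijB1$i, ijB2$i, ijD1$i, ijD2$i),
    j = c(ij11$j, ij12$j, ij21$j, ij22$j, ijB1$j, ijB2$j, ijD1$j, ijD2$j),
    x = c(as.vector(k11), as.vector(k12), as.vector(k21), as.vector(k22),
          -as.vector(gxp), -as.vector(gyp), as.vector(gxp), as.vector(gyp)),
    conv_idx = list(ij11 = ij11, ij22 = ij22),
    mass_local = mass,
    div_idx = list(ijD1 = ijD1, ijD2 = ijD2, gxp = gxp, gyp = gyp)
  )
}

assemble_convection_values <- function(p2m, pre, props, ux, uy) {
  t2 <- p2m$t2
  m <- nrow(t2)
  rho <- props$density
  uxe <- matrix(ux[t2], m, 6)
  uye <- matrix(uy[t2], m, 6)
  out <- matrix(0, m, 36)
  for (q in seq_len(pre$nq)) {
    Nq <- pre$N[q, ]
    wx <- as.vector(uxe %*% Nq)
    wy <- as.vector(uye %*% Nq)
    adv <- pre$gx[[q]] * wx + pre$gy[[q]] * wy     # m x 6: (w . grad) N_b
    cf <- pre$w[q] * pre$detJ * rho
    for (b in seq_len(6)) {
      cols <- ((b - 1) * 6 + 1):(b * 6)
      out[, cols] <- out[, cols] + matrix(Nq, m, 6, byrow = TRUE) * (cf * adv[, b])
    }
  }
  as.vector(out)
}

# Dirichlet values for all constrained dofs at a given time
dirichlet_values <- function(p2m, props, inflow_bc, eca_bc, t, period) {
  n2 <- p2m$n_p2
  fix <- integer(0); val <- numeric(0)
  apply_profile <- function(info, mdot, sign = 1) {
    pr <- inflow_velocity_profile(mdot, info$width, props)
    v <- sign * pr$fun(info$y - info$center)
    list(ids = c(info$ids, info$ids + n2), vals = c(v, numeric(length(info$ids))))
  }
  info_in <- dirichlet_boundary_info(p2m, inflow_bc$tag)
  a <- apply_profile(info_in, bc_massflow_at(inflow_bc, t, period))
  fix <- c(fix, a$ids); val <- c(val, a$vals)
  if (!is.null(eca_bc)) {
    info_e <- dirichlet_boundary_info(p2m, eca_bc$tag)
    b <- apply_profile(info_e, bc_massflow_at(eca_bc, t, period))
    fix <- c(fix, b$ids); val <- c(val, b$vals)
  }
  # no-slip wall overrides any shared corner nodes
  wall <- p2m$boundary[p2m$boundary$tag == "wall", , drop = FALSE]
  wid <- unique(c(wall$n1, wall$n2, wall$mid))
  fix <- c(fix, wid, wid + n2); val <- c(val, numeric(2 * length(wid)))
  keep <- !duplicated(fix, fromLast = TRUE)
  ord <- fix[keep]
  list(fix = ord, val = val[keep][order(ord)] , fix_sorted = sort(ord))
}

solve_saddle <- function(A, rhs, fix, val, ndof) {
  free <- setdiff(seq_len(ndof), fix)
  x <- numeric(ndof)
  x[fix] <- val
  rhs_f <- rhs[free] - A[free, fix, drop = FALSE] %*% x[fix]
  x[free] <- as.numeric(Matrix::solve(A[free, free], rhs_f))
  x
}

#' Solve transient incompressible flow on a bifurcation mesh
#'
#' Incompressible Newtonian Navier-Stokes with Taylor-Hood elements; implicit
#' Euler in time; per-step Picard iteration terminating when the relative
#' velocity increment drops below `tol` or `max_iter` is reached (the latter
#' is logged, not fatal). No-slip walls, prescribed velocity profiles at the
#' inlet (and ECA outlet if given), traction-free zero-pressure ICA outlet.
#'
#' @param mesh a `flow_mesh`.
#' @param inflow_bc a `flow_bc` with a mass-flow `waveform` (CCA inlet).
#' @param eca_bc optional `flow_bc` for the ECA outlet (positive mass flow
#'   leaves the domain).
#' @param props `fluid_props`.
#' @param dt time step (s); default `T/100`.
#' @param n_cycles number of cardiac cycles to simulate; default 3 (the first
#'   cycle carries the start-from-rest transient). Fields
#'   are stored for the final cycle, wall shear for all cycles.
#' @param tol per-step Picard convergence criterion (relative velocity
#'   increment); default 1e-4.
#' @param max_iter Picard iteration limit per step; default 150.
#' @return an object of class `flow_solution`.
#' @export
solve_transient <- function(mesh, inflow_bc, eca_bc = NULL, props = fluid_props(),
                            dt = NULL, n_cycles = 3, tol = 1e-4, max_iter = 150) {
  if (!inherits(inflow_bc$massflow, "waveform")) {
    stop_module("flow_sim", "transient solve needs a massflow waveform inflow")
  }
  period <- inflow_bc$massflow$period
  nsteps <- if (is.null(dt)) 100L else max(4L, as.integer(round(period / dt)))
  dt <- period / nsteps
  run_flow_solver(mesh, inflow_bc, eca_bc, props, dt = dt, nsteps = nsteps,
                  n_cycles = n_cycles, tol = tol, max_iter = max_iter, period = period)
}

#' Solve steady incompressible flow (constant boundary conditions)
#'
#' Picard iteration on the steady equations; used for benchmark solutions and
#' as the infinite-time limit of [solve_transient()].
#'
#' @inheritParams solve_transient
#' @param inflow_bc a `flow_bc` with constant mass flow.
#' @return a `flow_solution` with a single stored state.
#' @export
solve_steady <- function(mesh, inflow_bc, eca_bc = NULL, props = fluid_props(),
                         tol = 1e-4, max_iter = 150) {
  run_flow_solver(mesh, inflow_bc, eca_bc, props, dt = NULL, nsteps = 1L,
                  n_cycles = 1L, tol = tol, max_iter = max_iter, period = NULL)
}

run_flow_solver <- function(mesh, inflow_bc, eca_bc, props, dt, nsteps, n_cycles,
                            tol, max_iter, period) {
  p2m <- p2_mesh(mesh)
  pre <- precompute_p2(p2m)
  n2 <- p2m$n_p2; n1 <- p2m$n_p1
  ndof <- 2L * n2 + n1
  const <- assemble_constant_part(p2m, pre, props, dt)
  rho <- props$density
  # consistent mass matrix (velocity scalar block) for the transient RHS
  Msc <- if (!is.null(dt)) {
    ij <- block_indices(p2m$t2)
    Matrix::sparseMatrix(i = ij$i, j = ij$j, x = as.vector(const$mass_local),
                         dims = c(n2, n2))
  } else NULL
  wallinfo <- wall_edge_info(p2m)
  tags <- unique(p2m$boundary$tag)
  ntotal <- if (is.null(dt)) 1L else nsteps * n_cycles
  u <- numeric(2L * n2)
  pvec <- numeric(n1)
  tau_all <- matrix(0, nrow(wallinfo$edges), ntotal + 1L)
  flux <- matrix(0, length(tags), ntotal + 1L, dimnames = list(tags, NULL))
  bpress <- matrix(0, length(tags), ntotal + 1L, dimnames = list(tags, NULL))
  picard_iters <- integer(ntotal)
  div_res <- numeric(ntotal)
  store_from <- if (is.null(dt)) 1L else (n_cycles - 1L) * nsteps + 1L
  Ustore <- matrix(0, 2L * n2, ntotal - store_from + 2L)
  Pstore <- matrix(0, n1, ntotal - store_from + 2L)
  cfl_warned <- FALSE

  div_mat <- {
    ij1 <- const$div_idx$ijD1; ij2 <- const$div_idx$ijD2
    Matrix::sparseMatrix(i = c(ij1$i - 2L * n2, ij2$i - 2L * n2),
                         j = c(ij1$j, ij2$j),
                         x = c(as.vector(const$div_idx$gxp), as.vector(const$div_idx$gyp)),
                         dims = c(n1, 2L * n2))
  }

  record_state <- function(col, u, pvec) {
    tau_all[, col] <<- wall_shear_values(p2m, wallinfo, props, u)
    for (tg in tags) {
      flux[tg, col] <<- boundary_flux(p2m, tg, u, rho)
      bpress[tg, col] <<- boundary_mean_pressure(p2m, tg, pvec)
    }
    if (col >= store_from) {
      Ustore[, col - store_from + 1L] <<- u
      Pstore[, col - store_from + 1L] <<- pvec
    }
  }
  record_state(1L, u, pvec)

  for (step in seq_len(ntotal)) {
    t_new <- if (is.null(dt)) 0 else step * dt
    dv <- dirichlet_values(p2m, props, inflow_bc, eca_bc, t_new, period)
    rhs <- numeric(ndof)
    if (!is.null(dt)) {
      rhs[seq_len(n2)] <- as.numeric(Msc %*% u[seq_len(n2)]) * (rho / dt)
      rhs[n2 + seq_len(n2)] <- as.numeric(Msc %*% u[n2 + seq_len(n2)]) * (rho / dt)
    }
    u_it <- u
    iters <- 0L
    relax <- 1
    delta_prev <- Inf
    repeat {
      iters <- iters + 1L
      cv <- assemble_convection_values(p2m, pre, props, u_it[seq_len(n2)], u_it[n2 + seq_len(n2)])
      A <- Matrix::sparseMatrix(
        i = c(const$i, const$conv_idx$ij11$i, const$conv_idx$ij22$i),
        j = c(const$j, const$conv_idx$ij11$j, const$conv_idx$ij22$j),
        x = c(const$x, cv, cv), dims = c(ndof, ndof))
      x <- solve_saddle(A, rhs, dv$fix_sorted, dv$val, ndof)
      u_new <- x[seq_len(2L * n2)]
      delta <- sqrt(sum((u_new - u_it)^2)) / max(sqrt(sum(u_new^2)), 1e-300)
      # under-relax when the fixed-point iteration diverges or limit-cycles
      if (delta > delta_prev) {
        relax <- max(0.4, relax * 0.7)
      } else if (delta < 0.3 * delta_prev) {
        relax <- min(1, relax * 1.25)
      }
      u_it <- u_it + relax * (u_new - u_it)
      delta_prev <- delta
      pvec <- x[2L * n2 + seq_len(n1)]
      if (delta < tol || iters >= max_iter) break
    }
    if (iters >= max_iter) {
      message(sprintf("[flow_sim] Picard hit the iteration limit (%d) at step %d (delta %.2e)",
                      max_iter, step, delta))
    }
    u <- u_it
    picard_iters[step] <- iters
    div_res[step] <- sqrt(sum(as.numeric(div_mat %*% u)^2)) / max(sqrt(sum(u^2)), 1e-300)
    if (!is.null(dt) && !cfl_warned) {
      cfl <- dt * max(abs(u)) / mesh$h
      if (cfl > 5) {
        warning(sprintf("[flow_sim] CFL number %.1f exceeds 5; consider a smaller time step", cfl))
        cfl_warned <- TRUE
      }
    }
    record_state(step + 1L, u, pvec)
  }

  structure(list(
    p2 = p2m, mesh = mesh, props = props, dt = dt, nsteps = nsteps,
    n_cycles = n_cycles, period = period,
    times = if (is.null(dt)) 0 else seq(0, by = dt, length.out = ntotal + 1L),
    U = Ustore, P = Pstore, store_from = store_from,
    wall = wallinfo, tau = tau_all, flux = flux, boundary_pressure = bpress,
    picard_iters = picard_iters, div_residual = div_res
  ), class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("<flow_solution> %d dofs, %s, Picard iters %s, max div residual %.1e\n",
              2L * x$p2$n_p2 + x$p2$n_p1,
              if (is.null(x$dt)) "steady" else sprintf("dt=%.4g s, %d cycle(s)", x$dt, x$n_cycles),
              paste(range(x$picard_iters), collapse = "-"), max(x$div_residual)))
  invisible(x)
}

# --- wall shear extraction ---------------------------------------------------

# Precompute, for every wall boundary edge: adjacent element, P2 gradient at
# the edge midpoint, outward normal, streamwise tangent, length, arclength.
wall_edge_info <- function(p2m) {
  mesh <- p2m$mesh
  bnd <- p2m$boundary[p2m$boundary$tag == "wall", , drop = FALSE]
  t <- mesh$tris
  # adjacency: find the triangle containing each wall edge
  ek <- paste(pmin(bnd$n1, bnd$n2), pmax(bnd$n1, bnd$n2))
  all_e <- rbind(t[, c(1, 2)], t[, c(2, 3)], t[, c(3, 1)])
  all_k <- paste(pmin(all_e[, 1], all_e[, 2]), pmax(all_e[, 1], all_e[, 2]))
  tri_of <- ((match(ek, all_k) - 1L) %% nrow(t)) + 1L
  p <- mesh$nodes
  mid <- (p[bnd$n1, , drop = FALSE] + p[bnd$n2, , drop = FALSE]) / 2
  len <- sqrt((p[bnd$n2, 1] - p[bnd$n1, 1])^2 + (p[bnd$n2, 2] - p[bnd$n1, 2])^2)
  nw <- nrow(bnd)
  G <- matrix(0, nw, 12)  # gx (6) then gy (6) of P2 basis at the edge midpoint
  nvec <- matrix(0, nw, 2)
  for (r in seq_len(nw)) {
    e <- tri_of[r]
    v <- t[e, ]
    x1 <- p[v[1], ]; x2 <- p[v[2], ]; x3 <- p[v[3], ]
    J <- cbind(x2 - x1, x3 - x1)
    # reference coordinates of the midpoint
    xi <- solve(J, mid[r, ] - x1)
    sh <- p2_shapes(xi[1], xi[2])
    g_phys <- t(solve(t(J), t(sh$dN)))      # 6 x 2
    G[r, ] <- c(g_phys[, 1], g_phys[, 2])
    # outward normal: perpendicular to edge, pointing away from the opposite vertex
    ev <- p[bnd$n2[r], ] - p[bnd$n1[r], ]
    nr_ <- c(ev[2], -ev[1]) / sqrt(sum(ev^2))
    opp <- v[!(v %in% c(bnd$n1[r], bnd$n2[r]))][1]
    if (sum(nr_ * (p[opp, ] - mid[r, ])) > 0) nr_ <- -nr_
    nvec[r, ] <- nr_
  }
  # streamwise tangent: fixed sign convention (positive x, ties positive y)
  tvec <- cbind(-nvec[, 2], nvec[, 1])
  flip <- tvec[, 1] < 0 | (abs(tvec[, 1]) < 1e-12 & tvec[, 2] < 0)
  tvec[flip, ] <- -tvec[flip, ]
  ord <- order_wall_edges(bnd, mid, len)
  list(edges = bnd[ord$order, , drop = FALSE], tri = tri_of[ord$order],
       G = G[ord$order, , drop = FALSE], normal = nvec[ord$order, , drop = FALSE],
       tangent = tvec[ord$order, , drop = FALSE], len = len[ord$order],
       mid = mid[ord$order, , drop = FALSE], arclength = ord$arclength,
       t2rows = p2m$t2[tri_of[ord$order], , drop = FALSE])
}

# group wall edges into connected chains and assign a strictly increasing
# arc-length coordinate (edge midpoints), concatenating chains
order_wall_edges <- function(bnd, mid, len) {
  nw <- nrow(bnd)
  nodes <- unique(c(bnd$n1, bnd$n2))
  inc <- new.env(parent = emptyenv())
  for (r in seq_len(nw)) {
    for (v in c(bnd$n1[r], bnd$n2[r])) {
      key <- as.character(v)
      inc[[key]] <- c(inc[[key]], r)
    }
  }
  used <- logical(nw)
  order_out <- integer(0)
  arc <- numeric(0)
  s0 <- 0
  deg <- vapply(ls(inc), function(k) length(inc[[k]]), integer(1))
  endpoints <- as.integer(names(deg)[deg == 1])
  for (start_node in c(endpoints, nodes)) {
    key <- as.character(start_node)
    cand <- inc[[key]]
    cand <- cand[!used[cand]]
    if (!length(cand)) next
    cur_edge <- cand[1]
    cur_node <- start_node
    while (TRUE) {
      used[cur_edge] <- TRUE
      order_out <- c(order_out, cur_edge)
      arc <- c(arc, s0 + len[cur_edge] / 2)
      s0 <- s0 + len[cur_edge]
      nxt_node <- if (bnd$n1[cur_edge] == cur_node) bnd$n2[cur_edge] else bnd$n1[cur_edge]
      nxt <- inc[[as.character(nxt_node)]]
      nxt <- nxt[!used[nxt]]
      if (!length(nxt)) break
      cur_edge <- nxt[1]
      cur_node <- nxt_node
    }
    s0 <- s0 + mean(len)  # gap between chains keeps arclength strictly increasing
  }
  list(order = order_out, arclength = arc)
}

# signed scalar wall shear at every wall edge midpoint for velocity vector u
wall_shear_values <- function(p2m, wi, props, u) {
  n2 <- p2m$n_p2
  mu <- props$viscosity
  ue_x <- matrix(u[wi$t2rows], nrow(wi$t2rows), 6)
  ue_y <- matrix(u[wi$t2rows + n2], nrow(wi$t2rows), 6)
  gx <- wi$G[, 1:6]; gy <- wi$G[, 7:12]
  dux_dx <- rowSums(ue_x * gx); dux_dy <- rowSums(ue_x * gy)
  duy_dx <- rowSums(ue_y * gx); duy_dy <- rowSums(ue_y * gy)
  # tangential traction exerted by the fluid on the wall: the wall-side
  # normal is minus the fluid outward normal, so flip the sign to make
  # streamwise-forward drag positive
  e11 <- dux_dx; e22 <- duy_dy; e12 <- (dux_dy + duy_dx) / 2
  tx <- 2 * mu * (e11 * wi$normal[, 1] + e12 * wi$normal[, 2])
  ty <- 2 * mu * (e12 * wi$normal[, 1] + e22 * wi$normal[, 2])
  -(tx * wi$tangent[, 1] + ty * wi$tangent[, 2])
}

boundary_flux <- function(p2m, tag, u, rho) {
  bnd <- p2m$boundary[p2m$boundary$tag == tag, , drop = FALSE]
  if (!nrow(bnd)) return(NA_real_)
  p <- p2m$coords
  n2 <- p2m$n_p2
  ev <- p[bnd$n2, , drop = FALSE] - p[bnd$n1, , drop = FALSE]
  len <- sqrt(rowSums(ev^2))
  nx <- ev[, 2] / len; ny <- -ev[, 1] / len
  un <- function(id) u[id] * nx + u[id + n2] * ny
  # Simpson rule along each straight quadratic edge (exact for P2 traces)
  sum(rho * len / 6 * (un(bnd$n1) + 4 * un(bnd$mid) + un(bnd$n2)))
}

boundary_mean_pressure <- function(p2m, tag, pvec) {
  bnd <- p2m$boundary[p2m$boundary$tag == tag, , drop = FALSE]
  if (!nrow(bnd)) return(NA_real_)
  p <- p2m$coords
  len <- sqrt(rowSums((p[bnd$n2, , drop = FALSE] - p[bnd$n1, , drop = FALSE])^2))
  sum(len * (pvec[bnd$n1] + pvec[bnd$n2]) / 2) / sum(len)
}

#' Extract the final-cycle wall shear record from a flow solution
#'
#' @param sol a `flow_solution`.
#' @param mesh unused; kept so the record can be requested with the mesh at
#'   hand (the solution stores its mesh).
#' @return a `wall_shear_record` spanning exactly one cycle.
#' @export
wall_shear_series <- function(sol, mesh = NULL) {
  stopifnot(inherits(sol, "flow_solution"))
  if (is.null(sol$dt)) {
    return(wall_shear_record(sol$wall$arclength, sol$tau[, ncol(sol$tau), drop = FALSE],
                             0, Inf))
  }
  cols <- (ncol(sol$tau) - sol$nsteps):ncol(sol$tau)
  times <- seq(0, sol$period, length.out = sol$nsteps + 1L)
  wall_shear_record(sol$wall$arclength, sol$tau[, cols, drop = FALSE], times, sol$period)
}

#' Per-boundary mean gauge pressure traces over the final cycle
#'
#' Edge-length-averaged pressure on each tagged boundary per stored timestep.
#'
#' @param sol a `flow_solution`.
#' @param mesh unused (the solution stores its mesh).
#' @return list with `times` and one gauge-pressure trace (Pa) per tag, the
#'   inlet/outlet tags aliased as `cca`, `ica`, `eca`.
#' @export
boundary_pressure_series <- function(sol, mesh = NULL) {
  stopifnot(inherits(sol, "flow_solution"))
  bp <- sol$boundary_pressure
  cols <- if (is.null(sol$dt)) ncol(bp) else (ncol(bp) - sol$nsteps):ncol(bp)
  out <- list(times = if (is.null(sol$dt)) 0 else seq(0, sol$period, length.out = sol$nsteps + 1L))
  out$cca <- as.numeric(bp["inlet", cols])
  if ("outlet_ica" %in% rownames(bp)) out$ica <- as.numeric(bp["outlet_ica", cols])
  if ("outlet_eca" %in% rownames(bp)) out$eca <- as.numeric(bp["outlet_eca", cols])
  out
}

#' Evaluate the stored velocity field at a point
#'
#' @param sol a `flow_solution`.
#' @param xy numeric length-2 point.
#' @param col stored time column (default: last).
#' @return velocity vector (ux, uy) at the point.
#' @export
evaluate_velocity <- function(sol, xy, col = ncol(sol$U)) {
  p2m <- sol$p2
  mesh <- sol$mesh
  t <- mesh$tris; p <- mesh$nodes
  for (e in seq_len(nrow(t))) {
    x1 <- p[t[e, 1], ]; x2 <- p[t[e, 2], ]; x3 <- p[t[e, 3], ]
    J <- cbind(x2 - x1, x3 - x1)
    xi <- solve(J, xy - x1)
    if (xi[1] >= -1e-10 && xi[2] >= -1e-10 && sum(xi) <= 1 + 1e-10) {
      sh <- p2_shapes(xi[1], xi[2])
      ids <- p2m$t2[e, ]
      return(c(sum(sol$U[ids, col] * sh$N),
               sum(sol$U[ids + p2m$n_p2, col] * sh$N)))
    }
  }
  stop_module("flow_sim", "point (%.3g, %.3g) lies outside the mesh", xy[1], xy[2])
}

#' Cycle-to-cycle TAWSS periodicity of a transient solution
#'
#' Relative difference in per-point TAWSS between the last two simulated
#' cycles; small values justify computing metrics on the final cycle.
#'
#' @param sol a `flow_solution` with at least two cycles.
#' @return relative L2 difference of the last two cycle TAWSS fields.
#' @export
cycle_periodicity <- function(sol) {
  stopifnot(inherits(sol, "flow_solution"), !is.null(sol$dt), sol$n_cycles >= 2)
  ns <- sol$nsteps
  times <- seq(0, sol$period, length.out = ns + 1L)
  last <- (ncol(sol$tau) - ns):ncol(sol$tau)
  prev <- last - ns
  t1 <- tawss(wall_shear_record(sol$wall$arclength, sol$tau[, prev, drop = FALSE], times, sol$period))
  t2 <- tawss(wall_shear_record(sol$wall$arclength, sol$tau[, last, drop = FALSE], times, sol$period))
  sqrt(sum((t2 - t1)^2)) / max(sqrt(sum(t2^2)), 1e-300)
}
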