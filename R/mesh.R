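# Structured triangular meshing of channel-block geometries, plus mesh
# validation shared with the structural mesher.
#
# Every geometry describes one or more swept blocks: for each x-column the
# block occupies the vertical interval [lo(x), hi(x)]. Blocks are meshed as
# tensor grids of quads split into triangles; coincident nodes on shared
# block interfaces (the CCA midline up to the apex) are merged, which makes
# the mesh conforming across blocks.

#' Mesh a channel-block geometry into triangles
#'
#' @param geom a `bifurcation_geometry` or `channel_geometry`.
#' @param h_max maximum element circumdiameter (m). Default 0.16 mm.
#' @return an object of class `flow_mesh` with nodes, positively oriented
#'   triangles, and tagged boundary edges
#'   (`inlet`, `outlet_ica`, `outlet_eca`, `wall`).
#' @export
mesh_domain <- function(geom, h_max = 1.6e-4) {
  if (!is.list(geom$blocks)) stop_module("flow_sim", "geometry does not describe channel blocks")
  if (!is.numeric(h_max) || h_max <= 0) stop_module("flow_sim", "h_max must be > 0")
  dx <- h_max / sqrt(2) / 1.15
  nodes_all <- NULL
  tris_all <- NULL
  bnd_all <- NULL
  key_of <- function(x, y) paste(formatC(x, digits = 15, format = "e"),
                                 formatC(y, digits = 15, format = "e"))
  node_index <- new.env(parent = emptyenv())
  n_nodes <- 0L
  nodes_list <- list()
  add_nodes <- function(xy) {
    ids <- integer(nrow(xy))
    keys <- key_of(xy[, 1], xy[, 2])
    for (r in seq_len(nrow(xy))) {
      id <- node_index[[keys[r]]]
      if (is.null(id)) {
        n_nodes <<- n_nodes + 1L
        id <- n_nodes
        node_index[[keys[r]]] <- id
        nodes_list[[id]] <<- xy[r, ]
      }
      ids[r] <- id
    }
    ids
  }

  for (blk in geom$blocks) {
    # x-columns: piecewise-uniform between knots, spacing <= dx
    knots <- sort(unique(blk$x_knots))
    xs <- unlist(lapply(seq_len(length(knots) - 1), function(k) {
      n <- max(1, ceiling((knots[k + 1] - knots[k]) / dx))
      seq(knots[k], knots[k + 1], length.out = n + 1)[-(n + 1)]
    }))
    xs <- c(xs, knots[length(knots)])
    lo <- blk$lo(xs); hi <- blk$hi(xs)
    if (any(hi <= lo)) stop_module("flow_sim", "meshing failure: degenerate width in block '%s'", blk$name)
    nt <- max(3, ceiling(max(hi - lo) / dx) + 1L)
    ncol_ <- length(xs)
    frac <- (seq_len(nt) - 1) / (nt - 1)
    gx <- rep(xs, each = nt)
    # convex combination is exact at both endpoints, so shared block
    # interfaces (frac 0 / 1) merge bit-identically
    gy <- as.vector(vapply(seq_len(ncol_), function(i) lo[i] * (1 - frac) + hi[i] * frac,
                           numeric(nt)))
    ids <- matrix(add_nodes(cbind(gx, gy)), nrow = nt, ncol = ncol_)

    # quads -> triangles, choosing the shorter diagonal to limit circumdiameter
    coords <- do.call(rbind, nodes_list)
    tri_block <- vector("list", ncol_ - 1L)
    for (i in seq_len(ncol_ - 1L)) {
      a <- ids[-nt, i]; b <- ids[-nt, i + 1L]; c2 <- ids[-1L, i + 1L]; d2 <- ids[-1L, i]
      dAC <- (coords[a, 1] - coords[c2, 1])^2 + (coords[a, 2] - coords[c2, 2])^2
      dBD <- (coords[b, 1] - coords[d2, 1])^2 + (coords[b, 2] - coords[d2, 2])^2
      useAC <- dAC <= dBD
      # diagonal a-c2: (a,b,c2) + (a,c2,d2); diagonal b-d2: (a,b,d2) + (b,c2,d2)
      tri1 <- cbind(a, b, ifelse(useAC, c2, d2))
      tri2 <- cbind(ifelse(useAC, a, b), c2, d2)
      tri_block[[i]] <- rbind(tri1, tri2)
    }
    tris_all <- rbind(tris_all, do.call(rbind, tri_block))

    # boundary edges
    xm_col <- (xs[-1] + xs[-ncol_]) / 2
    bnd <- list()
    if (!is.na(blk$tag_left)) {
      bnd[[length(bnd) + 1]] <- data.frame(n1 = ids[-nt, 1], n2 = ids[-1, 1], tag = blk$tag_left)
    }
    if (!is.na(blk$tag_right)) {
      bnd[[length(bnd) + 1]] <- data.frame(n1 = ids[-nt, ncol_], n2 = ids[-1, ncol_], tag = blk$tag_right)
    }
    tb <- blk$tag_bottom(xm_col)
    sel <- !is.na(tb)
    if (any(sel)) {
      bnd[[length(bnd) + 1]] <- data.frame(n1 = ids[1, -ncol_][sel], n2 = ids[1, -1][sel], tag = tb[sel])
    }
    tt <- blk$tag_top(xm_col)
    sel <- !is.na(tt)
    if (any(sel)) {
      bnd[[length(bnd) + 1]] <- data.frame(n1 = ids[nt, -ncol_][sel], n2 = ids[nt, -1][sel], tag = tt[sel])
    }
    bnd_all <- rbind(bnd_all, do.call(rbind, bnd))
  }
  nodes <- do.call(rbind, nodes_list)
  m <- structure(list(nodes = nodes, tris = tris_all, boundary = bnd_all,
                      h_max = h_max, geom_class = class(geom)[1]),
                 class = c("flow_mesh", "fem_mesh"))
  orient_and_validate_mesh(m, h_max = h_max)
}

# ensure positive orientation, then validate boundary topology and size bound
orient_and_validate_mesh <- function(m, h_max = NULL) {
  p <- m$nodes; t <- m$tris
  ax <- p[t[, 1], 1]; ay <- p[t[, 1], 2]
  bx <- p[t[, 2], 1]; by <- p[t[, 2], 2]
  cx <- p[t[, 3], 1]; cy <- p[t[, 3], 2]
  area2 <- (bx - ax) * (cy - ay) - (cx - ax) * (by - ay)
  flip <- area2 < 0
  if (any(flip)) {
    tmp <- m$tris[flip, 2]
    m$tris[flip, 2] <- m$tris[flip, 3]
    m$tris[flip, 3] <- tmp
  }
  if (any(abs(area2) < .Machine$double.eps * 100)) {
    stop_module("flow_sim", "meshing failure: degenerate (zero-area) element")
  }
  validate_fem_mesh(m, h_max)
}

#' Validate a finite-element mesh
#'
#' Checks positive orientation, watertight boundary topology (every boundary
#' edge tagged exactly once, no interior edge tagged) and, if `h_max` is
#' given, the element circumdiameter bound.
#'
#' @param m a `flow_mesh` or `structural_mesh`.
#' @param h_max optional circumdiameter bound (m).
#' @return the mesh, invisibly enriched with `h` (max circumdiameter).
#' @export
validate_fem_mesh <- function(m, h_max = NULL) {
  p <- m$nodes; t <- m$tris
  ax <- p[t[, 1], 1]; ay <- p[t[, 1], 2]
  bx <- p[t[, 2], 1]; by <- p[t[, 2], 2]
  cx <- p[t[, 3], 1]; cy <- p[t[, 3], 2]
  area2 <- (bx - ax) * (cy - ay) - (cx - ax) * (by - ay)
  if (any(area2 <= 0)) stop_module("flow_sim", "mesh has non-positively-oriented elements")
  la <- sqrt((bx - cx)^2 + (by - cy)^2)
  lb <- sqrt((ax - cx)^2 + (ay - cy)^2)
  lc <- sqrt((ax - bx)^2 + (ay - by)^2)
  circum <- la * lb * lc / area2  # = 2R
  m$h <- max(circum)
  if (!is.null(h_max) && m$h > h_max * (1 + 1e-9)) {
    stop_module("flow_sim", "element circumdiameter %.3g exceeds h_max %.3g", m$h, h_max)
  }
  # topological boundary: edges incident to exactly one triangle
  e <- rbind(t[, c(1, 2)], t[, c(2, 3)], t[, c(3, 1)])
  ek <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(ek)
  if (any(tab > 2)) stop_module("flow_sim", "non-manifold mesh: edge shared by >2 elements")
  bnd_topo <- names(tab)[tab == 1]
  bk <- paste(pmin(m$boundary$n1, m$boundary$n2), pmax(m$boundary$n1, m$boundary$n2))
  if (anyDuplicated(bk)) stop_module("flow_sim", "boundary edge tagged more than once")
  if (!setequal(bnd_topo, bk)) {
    miss <- setdiff(bnd_topo, bk)
    extra <- setdiff(bk, bnd_topo)
    if (length(miss)) stop_module("flow_sim", "untagged boundary edge(s): %d missing", length(miss))
    stop_module("flow_sim", "tagged edge(s) not on the boundary: %d", length(extra))
  }
  invisible(m)
}

#' @export
print.flow_mesh <- function(x, ...) {
  cat(sprintf("<flow_mesh> %d nodes, %d triangles, h = %.3g m (bound %.3g)\n",
              nrow(x$nodes), nrow(x$tris), x$h %||% NA, x$h_max))
  cat("  boundary edges:", paste(sprintf("%s=%d", names(table(x$boundary$tag)),
                                         table(x$boundary$tag)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.structural_mesh <- function(x, ...) {
  cat(sprintf("<structural_mesh> %d nodes, %d triangles (%d plaque), face size %.3g m\n",
              nrow(x$nodes), nrow(x$tris), sum(x$region == "plaque"), x$face_size))
  invisible(x)
}

#' Write a mesh and optional nodal fields in legacy VTK ASCII format
#'
#' @param m a mesh (`flow_mesh` or `structural_mesh`).
#' @param path output file path.
#' @param point_data named list of per-node numeric vectors (optional).
#' @export
write_mesh_vtk <- function(m, path, point_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(m$nodes)
  writeLines(c("# vtk DataFile Version 3.0", "carotidrisk mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g 0", m$nodes[, 1], m$nodes[, 2]), con)
  ne <- nrow(m$tris)
  writeLines(sprintf("CELLS %d %d", ne, 4 * ne), con)
  writeLines(sprintf("3 %d %d %d", m$tris[, 1] - 1L, m$tris[, 2] - 1L, m$tris[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("5", ne), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", point_data[[nm]]), con)
    }
  }
  invisible(path)
}
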