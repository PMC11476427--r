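# Shared finite-element machinery: triangle quadrature, quadratic (P2)
# Lagrange basis, P2 node numbering, and vectorized per-element precomputation.
# The flow solver uses the Taylor-Hood P2/P1 pair; the structural solver uses
# P2 displacements.

# Gauss rules on the reference triangle (weights sum to 1/2 = reference area)
tri_quad_rule <- function(degree = 5) {
  if (degree <= 2) {
    # 3-point midpoint rule, degree 2
    pts <- matrix(c(0.5, 0, 0.5, 0.5, 0, 0.5), ncol = 2, byrow = TRUE)
    w <- rep(1 / 6, 3)
  } else if (degree <= 4) {
    # 6-point Dunavant rule, degree 4
    a1 <- 0.445948490915965; b1 <- 0.108103018168070
    a2 <- 0.091576213509771; b2 <- 0.816847572980459
    pts <- matrix(c(a1, a1, b1, a1, a1, b1,
                    a2, a2, b2, a2, a2, b2), ncol = 2, byrow = TRUE)
    w <- c(rep(0.223381589678011, 3), rep(0.109951743655322, 3)) / 2
  } else {
    # 7-point rule, degree 5
    a <- 0.059715871789770; b <- 0.470142064105115
    c2 <- 0.797426985353087; d2 <- 0.101286507323456
    pts <- rbind(c(1 / 3, 1 / 3),
                 c(a, b), c(b, a), c(b, b),
                 c(c2, d2), c(d2, c2), c(d2, d2))
    w <- c(0.225, rep(0.132394152788506, 3), rep(0.125939180544827, 3)) / 2
  }
  list(pts = pts, w = w)
}

# P2 basis at reference point (xi, eta); returns N (6) and dN (6 x 2)
p2_shapes <- function(xi, eta) {
  l1 <- 1 - xi - eta; l2 <- xi; l3 <- eta
  N <- c(l1 * (2 * l1 - 1), l2 * (2 * l2 - 1), l3 * (2 * l3 - 1),
         4 * l1 * l2, 4 * l2 * l3, 4 * l3 * l1)
  d1 <- c(-1, -1); d2_ <- c(1, 0); d3 <- c(0, 1)
  dN <- rbind((4 * l1 - 1) * d1,
              (4 * l2 - 1) * d2_,
              (4 * l3 - 1) * d3,
              4 * (l2 * d1 + l1 * d2_),
              4 * (l3 * d2_ + l2 * d3),
              4 * (l1 * d3 + l3 * d1))
  list(N = N, dN = dN)
}

# P1 basis at reference point
p1_shapes <- function(xi, eta) c(1 - xi - eta, xi, eta)

# Build the P2 node numbering: vertex nodes keep their ids, one new node per
# unique edge. Returns the enriched mesh description.
p2_mesh <- function(mesh) {
  t <- mesh$tris
  n1 <- nrow(mesh$nodes)
  e <- rbind(t[, c(1, 2)], t[, c(2, 3)], t[, c(3, 1)])
  ek <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  uk <- unique(ek)
  eid <- match(ek, uk)
  ue <- e[!duplicated(ek), , drop = FALSE]
  mid <- (mesh$nodes[ue[, 1], , drop = FALSE] + mesh$nodes[ue[, 2], , drop = FALSE]) / 2
  m <- nrow(t)
  t2 <- cbind(t, n1 + matrix(eid, nrow = m, ncol = 3))
  coords <- rbind(mesh$nodes, mid)
  # P2 ids of tagged boundary edges (vertex, vertex, midpoint)
  bnd <- mesh$boundary
  bk <- paste(pmin(bnd$n1, bnd$n2), pmax(bnd$n1, bnd$n2))
  bnd$mid <- n1 + match(bk, uk)
  list(mesh = mesh, t2 = t2, coords = coords, n_p1 = n1, n_p2 = nrow(coords),
       boundary = bnd)
}

# Per-element geometry and basis gradients at every quadrature point.
# Returns detJ (m), and per-q lists gx, gy (m x 6 matrices), plus N (q x 6).
precompute_p2 <- function(p2m, rule = tri_quad_rule(5)) {
  mesh <- p2m$mesh
  t <- mesh$tris
  p <- mesh$nodes
  j11 <- p[t[, 2], 1] - p[t[, 1], 1]; j12 <- p[t[, 3], 1] - p[t[, 1], 1]
  j21 <- p[t[, 2], 2] - p[t[, 1], 2]; j22 <- p[t[, 3], 2] - p[t[, 1], 2]
  detJ <- j11 * j22 - j12 * j21
  # inverse transpose entries: grad_phys = invJ^T %*% grad_ref
  it11 <- j22 / detJ; it12 <- -j21 / detJ
  it21 <- -j12 / detJ; it22 <- j11 / detJ
  nq <- length(rule$w)
  gx <- vector("list", nq); gy <- vector("list", nq)
  N <- matrix(0, nq, 6); P1 <- matrix(0, nq, 3)
  for (q in seq_len(nq)) {
    sh <- p2_shapes(rule$pts[q, 1], rule$pts[q, 2])
    N[q, ] <- sh$N
    P1[q, ] <- p1_shapes(rule$pts[q, 1], rule$pts[q, 2])
    # outer products: (m x 6) = it .* ref gradients
    gx[[q]] <- outer(it11, sh$dN[, 1]) + outer(it12, sh$dN[, 2])
    gy[[q]] <- outer(it21, sh$dN[, 1]) + outer(it22, sh$dN[, 2])
  }
  list(detJ = detJ, gx = gx, gy = gy, N = N, P1 = P1, w = rule$w, nq = nq)
}

# Triplet index vectors for a block of 6x6 element matrices
block_indices <- function(t2, row_offset = 0L, col_offset = 0L, rows = t2, cols = t2) {
  m <- nrow(rows)
  i <- rep.int(seq_len(ncol(rows)), ncol(cols))
  j <- rep(seq_len(ncol(cols)), each = ncol(rows))
  list(i = as.vector(rows[, i]) + row_offset,
       j = as.vector(cols[, j]) + col_offset)
}

# Accumulate sum_q w * detJ * (A_q[,i] * B_q[,j]) into an m x (na*nb) matrix
# of local blocks; A_q, B_q are lists over quadrature points of m x na / m x nb
outer_accumulate <- function(w, detJ, A, B, coefs = NULL) {
  m <- nrow(A[[1]]); na <- ncol(A[[1]]); nb <- ncol(B[[1]])
  out <- matrix(0, m, na * nb)
  for (q in seq_along(w)) {
    cf <- if (is.null(coefs)) w[q] * detJ else w[q] * detJ * coefs[[q]]
    Aq <- A[[q]]; Bq <- B[[q]]
    for (b in seq_len(nb)) {
      out[, ((b - 1) * na + 1):(b * na)] <- out[, ((b - 1) * na + 1):(b * na)] +
        Aq * (cf * Bq[, b])
    }
  }
  out
}
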