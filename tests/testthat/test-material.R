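random_admissible_F <- function() {
  repeat {
    F <- diag(3) + matrix(runif(9, -0.25, 0.25), 3, 3)
    if (det(F) > 0.3) return(F)
  }
}

test_that("identity deformation gives zero stress and zero energy", {
  for (mat in list(arterial_wall_material(), fibrosis_material())) {
    expect_equal(strain_energy(mat, diag(3)), 0)
    expect_equal(max(abs(mooney_rivlin_stress(mat, diag(3)))), 0, tolerance = 1e-12)
  }
})

test_that("analytic stress matches finite differences of the energy", {
  set.seed(14)
  mats <- list(arterial_wall_material(), fibrosis_material())
  for (k in 1:10) {
    mats[[length(mats) + 1]] <- material_mr(
      c10 = runif(1, 0.01e6, 1e6), c01 = runif(1, 0, 1e6), c20 = runif(1, -1e6, 5e6),
      c11 = runif(1, -2e6, 2e6), c02 = runif(1, 0, 2e6), c21 = runif(1, 0, 1e6),
      d = 10^runif(1, -7, -4))
  }
  for (mat in mats) {
    F <- random_admissible_F()
    C <- t(F) %*% F
    S <- carotidrisk:::mr_second_pk(mat, C)
    h <- 1e-6
    S_fd <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      Cp <- C; Cm <- C
      Cp[i, j] <- Cp[i, j] + h
      Cm[i, j] <- Cm[i, j] - h
      S_fd[i, j] <- 2 * (carotidrisk:::mr_energy_C(mat, Cp) - carotidrisk:::mr_energy_C(mat, Cm)) / (2 * h)
    }
    expect_lt(max(abs(S - S_fd)) / max(abs(S)), 1e-6)
  }
})

test_that("neo-Hookean isochoric uniaxial stretch matches the closed form", {
  mat <- material_mr(c10 = 0.07e6, d = 1e-5)
  lam <- 1.2
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  sig <- mooney_rivlin_stress(mat, F)
  # axial-minus-lateral Cauchy stress difference: 2 C10 (lam^2 - 1/lam)
  expected <- 2 * 0.07e6 * (lam^2 - 1 / lam)
  expect_equal(sig[1, 1] - sig[2, 2], expected, tolerance = 1e-8)
  expect_equal(expected, 0.0849e6, tolerance = 1e-3)
})

test_that("Cauchy stress is symmetric for random admissible gradients", {
  set.seed(5)
  mat <- arterial_wall_material()
  for (k in 1:1000) {
    F <- random_admissible_F()
    s <- mooney_rivlin_stress(mat, F)
    expect_lt(max(abs(s - t(s))), 1e-8 * max(abs(s), 1))
  }
})

test_that("superposed rigid rotation leaves principal stresses unchanged", {
  set.seed(8)
  mat <- fibrosis_material()
  for (k in 1:20) {
    F <- random_admissible_F()
    th <- runif(1, 0, 2 * pi); ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    Kx <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
    Q <- diag(3) + sin(th) * Kx + (1 - cos(th)) * Kx %*% Kx
    s1 <- sort(eigen(mooney_rivlin_stress(mat, F), symmetric = TRUE)$values)
    s2 <- sort(eigen(mooney_rivlin_stress(mat, Q %*% F), symmetric = TRUE)$values)
    expect_lt(max(abs(s1 - s2)) / max(abs(s1)), 1e-10)
    expect_equal(strain_energy(mat, Q %*% F), strain_energy(mat, F),
                 tolerance = 1e-12)
  }
})

test_that("plane-strain vectorized constitutive path agrees with the 3x3 path", {
  set.seed(23)
  for (mat in list(arterial_wall_material(), fibrosis_material())) {
    F2 <- diag(2) + matrix(runif(4, -0.2, 0.2), 2, 2)
    if (det(F2) <= 0) F2 <- diag(2)
    C2 <- t(F2) %*% F2
    Sps <- carotidrisk:::mr_stress_ps(mat, C2[1, 1], C2[1, 2], C2[2, 2])
    F3 <- carotidrisk:::embed_F(F2)
    S3 <- carotidrisk:::mr_second_pk(mat, t(F3) %*% F3)
    expect_equal(c(Sps$S11, Sps$S12, Sps$S22, Sps$S33),
                 c(S3[1, 1], S3[1, 2], S3[2, 2], S3[3, 3]), tolerance = 1e-10)
  }
})

test_that("degenerate deformation gradients are rejected", {
  mat <- arterial_wall_material()
  expect_error(mooney_rivlin_stress(mat, diag(c(-1, 1, 1))), "positive determinant")
  expect_error(material_mr(c10 = -1e6, d = 1e-5), "shear modulus")
  expect_error(material_mr(c10 = 1e5, d = -1), "d must be > 0")
})
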