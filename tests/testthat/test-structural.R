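test_that("zero pressure gives zero displacement and stress", {
  cs <- cross_section_geometry(2e-3, 1e-3)
  m <- mesh_cross_section(cs, face_size = 5e-4)
  sol <- solve_structural(m, list(wall = arterial_wall_material()), 0)
  expect_equal(max(sol$displacement_magnitude), 0)
  expect_equal(max(abs(sol$principal_max)), 0)
  ps <- plaque_structural_stress(sol)
  expect_equal(ps$pss, 0)
  expect_equal(ps$max_deformation, 0)
})

test_that("pressurized neo-Hookean ring matches the Lame linear-limit solution", {
  fx <- lame_fixture()
  sol <- fx$sol
  mu <- 2 * 0.07e6; kap <- 2 / 1e-5; lam <- kap - 2 * mu / 3
  A <- -fx$p / (2 * (lam + mu) + 2 * mu * fx$b^2 / fx$a^2)
  B <- -A * fx$b^2
  cen <- sol$element_centroid
  r <- sqrt(rowSums(cen^2)); phi <- atan2(cen[, 2], cen[, 1])
  sc <- sol$stress_components
  hoop <- sc[, 1] * sin(phi)^2 - 2 * sc[, 2] * sin(phi) * cos(phi) + sc[, 3] * cos(phi)^2
  radial <- sc[, 1] * cos(phi)^2 + 2 * sc[, 2] * sin(phi) * cos(phi) + sc[, 3] * sin(phi)^2
  hoop_an <- 2 * lam * A + 2 * mu * (A + B / r^2)
  rad_an <- 2 * lam * A + 2 * mu * (A - B / r^2)
  expect_lt(max(abs(hoop - hoop_an)) / max(abs(hoop_an)), 0.05)
  expect_lt(max(abs(radial - rad_an)) / max(abs(rad_an)), 0.05)
  # radial displacement at the inner boundary
  expect_equal(max(sol$displacement_magnitude), abs(A * fx$a + B / fx$a), tolerance = 0.02)
  # frictionless support: normal displacement of the outer boundary is zero
  expect_lt(sol$outer_normal_disp, 1e-12)
  expect_lt(sol$residual, 1e-6)
})

test_that("axisymmetric load on a symmetric ring gives axisymmetric stress", {
  fx <- lame_fixture()
  sol <- fx$sol
  cen <- sol$element_centroid
  r <- round(sqrt(rowSums(cen^2)), 9)
  phi <- atan2(cen[, 2], cen[, 1])
  sc <- sol$stress_components
  hoop <- sc[, 1] * sin(phi)^2 - 2 * sc[, 2] * sin(phi) * cos(phi) + sc[, 3] * cos(phi)^2
  spread <- vapply(split(hoop, r), function(z) (max(z) - min(z)) / max(abs(mean(z)), 1e-9),
                   numeric(1))
  expect_lt(max(spread), 0.01)
})

test_that("doubling a small pressure doubles the deformation", {
  cs <- cross_section_geometry(2e-3, 1.2e-3,
                               plaque = list(theta0 = 0.4, arc = 110 * pi / 180,
                                             cap = 3e-4, thickness = 5e-4))
  m <- mesh_cross_section(cs, face_size = 5e-4)
  mats <- list(wall = arterial_wall_material(), plaque = fibrosis_material())
  s1 <- solve_structural(m, mats, 500, n_increments = 2)
  s2 <- solve_structural(m, mats, 1000, n_increments = 2)
  expect_equal(max(s2$displacement_magnitude) / max(s1$displacement_magnitude), 2,
               tolerance = 0.02)
})

test_that("plaque structural stress is monotone in the applied pressure", {
  cs <- cross_section_geometry(2e-3, 1.2e-3,
                               plaque = list(theta0 = 0.4, arc = 110 * pi / 180,
                                             cap = 3e-4, thickness = 5e-4))
  m <- mesh_cross_section(cs, face_size = 5e-4)
  mats <- list(wall = arterial_wall_material(), plaque = fibrosis_material())
  pss <- vapply(c(4000, 10000, 16000),
                function(p) plaque_structural_stress(solve_structural(m, mats, p, n_increments = 3))$pss,
                numeric(1))
  expect_true(all(diff(pss) > 0))
})

test_that("a thin fibrous cap concentrates more stress than a thick one", {
  mats <- list(wall = arterial_wall_material(), plaque = fibrosis_material())
  mk <- function(cap) {
    cs <- cross_section_geometry(2e-3, 1.2e-3,
                                 plaque = list(theta0 = 0.4, arc = 110 * pi / 180,
                                               cap = cap, thickness = 6e-4))
    mesh_cross_section(cs, face_size = 4.5e-4)
  }
  thin <- plaque_structural_stress(solve_structural(mk(1.5e-4), mats, 16000, n_increments = 4))
  thick <- plaque_structural_stress(solve_structural(mk(4.5e-4), mats, 16000, n_increments = 4))
  expect_gt(thin$pss, thick$pss)
})

test_that("generated plaque case converges with PSS at the cap or plaque", {
  fx <- structural_fixture()
  sol <- fx$sol
  expect_lt(sol$residual, 1e-6)
  expect_lt(sol$outer_normal_disp, 1e-12)
  ps <- plaque_structural_stress(sol)
  expect_gt(ps$pss, 0)
  expect_gt(ps$max_von_mises, 0)
  expect_true(ps$location$region %in% c("cap", "plaque"))
  expect_gt(ps$max_deformation, 0)
  expect_error(solve_structural(fx$mesh, list(wall = arterial_wall_material()), 1000),
               "no material for region")
})
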