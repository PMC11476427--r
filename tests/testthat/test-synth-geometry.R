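test_that("stenosis severity sets the minimal ICA lumen width", {
  g <- generate_geometry(c(cca = 6e-3, ica = 5e-3, eca = 3.5e-3),
                         stenosis_severity = 0.5, seed = 3)
  xs <- seq(0, g$l_branch, length.out = 2000)
  wmin <- min(g$blocks$upper$hi(xs) - g$blocks$upper$lo(xs))
  expect_equal(wmin, 2.5e-3, tolerance = 0.01)
})

test_that("zero severity leaves both branch widths at their reference", {
  g <- generate_geometry(stenosis_severity = 0, seed = 5)
  xs <- seq(0, g$l_branch, length.out = 500)
  expect_equal(max(abs(g$blocks$upper$hi(xs) - g$blocks$upper$lo(xs) - g$d_ica)), 0)
  expect_equal(max(abs(g$blocks$lower$hi(xs) - g$blocks$lower$lo(xs) - g$d_eca)), 0)
})

test_that("geometry generation is deterministic per seed and rejects severe stenosis", {
  g1 <- generate_geometry(stenosis_severity = 0.4, seed = 11)
  g2 <- generate_geometry(stenosis_severity = 0.4, seed = 11)
  expect_identical(g1$boundary, g2$boundary)
  g3 <- generate_geometry(stenosis_severity = 0.4, seed = 12)
  expect_false(identical(g1$boundary, g3$boundary))
  expect_error(generate_geometry(stenosis_severity = 0.95), "0.95")
})

test_that("geometry is scale-covariant: doubling lengths doubles coordinates", {
  g1 <- generate_geometry(c(cca = 6e-3, ica = 4.5e-3, eca = 3.5e-3), 0.3, seed = 7)
  g2 <- generate_geometry(c(cca = 12e-3, ica = 9e-3, eca = 7e-3), 0.3, seed = 7)
  expect_equal(g2$boundary, 2 * g1$boundary, tolerance = 1e-12)
})

test_that("boundary polygon is closed-walk and walls never cross the divider", {
  for (s in c(0, 0.3, 0.9)) {
    g <- generate_geometry(stenosis_severity = s, seed = 2)
    xs <- seq(1e-6, g$l_branch, length.out = 1000)
    expect_true(all(g$blocks$upper$lo(xs) >= g$blocks$lower$hi(xs) - 1e-12))
    expect_gt(abs(polygon_area <- sum(g$boundary[, 1])), 0)  # non-degenerate sample
  }
})

test_that("cross-section plaque area matches the analytic annular sector", {
  g <- generate_cross_section(wall_thickness = 1.5e-3, plaque_arc_extent = 120,
                              cap_thickness = 2e-4, seed = 9)
  p <- g$plaque
  analytic <- p$arc / 2 * (p$r_outer^2 - p$r_inner^2)
  shoelace <- abs(carotidrisk:::polygon_area(g$contours$plaques[[1]]))
  expect_equal(shoelace, analytic, tolerance = 0.02)
})

test_that("cross-section generation validates preconditions and is deterministic", {
  expect_error(generate_cross_section(plaque_arc_extent = 0), "non-degenerate")
  expect_error(generate_cross_section(plaque_arc_extent = 350), "330")
  expect_error(cross_section_geometry(2e-3, 1e-3,
                                      plaque = list(theta0 = 0, arc = 1, cap = 5e-4, thickness = 9e-4)),
               "inside the wall ring")
  g1 <- generate_cross_section(seed = 4)
  g2 <- generate_cross_section(seed = 4)
  expect_identical(g1$contours, g2$contours)
})

test_that("geometry and cross-section CSV writers emit readable files", {
  g <- generate_geometry(seed = 1)
  p1 <- file.path(tempdir(), "geom.csv")
  write_geometry_csv(g, p1)
  d <- read.csv(p1)
  expect_equal(nrow(d), nrow(g$boundary))
  cs <- generate_cross_section(seed = 1)
  p2 <- file.path(tempdir(), "cs.csv")
  write_cross_section_csv(cs, p2)
  d2 <- read.csv(p2)
  expect_setequal(unique(d2$region), c("lumen", "wall", "plaque"))
})
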